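case,age,sex,diagnosis,tumor_grade,recurrence,hemisphere,biopsies
1,52,M,Glioblastoma,4,New,Left,4
2,46,M,Oligodendroglioma,2,Recurrent,Bilateral,NA
3,65,F,Glioblastoma,4,New,Right,NA
4,60,M,Glioblastoma,4,Recurrent,Right,2
5,46,F,Glioblastoma,4,New,Right,NA
6,27,F,Oligodendroglioma,2,New,Right,NA
7,39,M,Astrocytoma,4,Recurrent,Left,NA
8,44,M,Glioblastoma,4,Recurrent,Left,4
9,37,M,Glioblastoma,4,Recurrent,Left,NA
10,60,M,Glioblastoma,4,Recurrent,Right,3
11,35,F,Glioblastoma,4,New,Left,3
12,40,M,Astrocytoma,2,Recurrent,Right,3
13,29,F,Astrocytoma,2,New,Left,NA
14,35,F,Astrocytoma,2,New,Right,5
15,50,F,Glioblastoma,4,New,Left,NA
16,37,F,Anaplastic Oligodendroglioma,3,Recurrent,Left,NA
17,55,M,Glioblastoma,4,New,Left,NA
18,46,M,Astrocytoma,2,New,Right,NA
19,78,F,Glioblastoma,4,New,Right,NA
20,58,M,Glioblastoma,4,Recurrent,Right,NA
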