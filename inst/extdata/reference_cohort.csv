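subject,age,sex,tumor_location,hemisphere,tumor_volume_cm3,diagnosis
1,34,M,Frontal,Left,98.1,Anaplastic Astrocytoma WHO Grade 3
2,51,F,Supplementary Motor Area,Right,45.3,Anaplastic Astrocytoma WHO Grade 3
3,47,M,Frontal,Left,129,Anaplastic Oligodendroglioma WHO Grade 3
4,40,F,Frontal,Left,207,Anaplastic Oligodendroglioma WHO Grade 3
5,25,M,Frontal,Left,10.1,Oligodendroglioma WHO Grade 2
6,36,F,Internal Capsule,Right,16.7,Glioblastoma WHO Grade 4
7,62,F,Subcentral,Right,6.67,Glioblastoma WHO Grade 4
8,59,F,Subcentral,Left,4,Glioblastoma WHO Grade 4
9,30,M,Supplementary Motor Area,Left,27.5,Astrocytoma WHO Grade 2
10,69,M,Fronto-Insular,Left,54.3,Glioblastoma WHO Grade 4
11,32,M,Temporo-Insular,Left,71.2,Anaplastic Oligodendroglioma WHO Grade 3
12,51,M,Temporo-Insular,Left,16.8,Glioblastoma WHO Grade 4
13,37,M,Temporo-Insular,Left,105.0,Anaplastic Oligodendroglioma WHO Grade 3
14,29,M,Temporo-Insular,Left,9.01,Astrocytoma WHO Grade 2
15,54,F,Frontal,Right,114.3,Astrocytoma WHO Grade 3
16,51,F,Frontal,Left,7.42,Oligodendroglioma WHO Grade 2
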