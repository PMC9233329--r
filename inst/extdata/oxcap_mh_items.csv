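item_number,question_number,label,reversed
1,1,Limitation in daily activities,FALSE
2,2,Social networks,TRUE
3,3,Losing sleep over worry,FALSE
4,4,Enjoying social and recreational activities,TRUE
5,5,Having suitable accommodation,FALSE
6,6,Feeling safe,TRUE
7,7,Likelihood of assault,FALSE
8,8,Likelihood of discrimination,FALSE
9,9a,Influencing local decisions,TRUE
10,9b,Freedom of expression,TRUE
11,9c,Appreciating nature,TRUE
12,9d,Respecting and valuing people,TRUE
13,9e,Enjoying friendship and support,TRUE
14,9f,Self-determination,TRUE
15,9g,Imagination and creativity,TRUE
16,9h,Access to interesting activities or employment,TRUE
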