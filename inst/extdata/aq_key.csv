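item,subscale,agree_scored
1,social_skills,FALSE
2,attention_switching,TRUE
3,imagination,FALSE
4,attention_switching,TRUE
5,attention_to_detail,TRUE
6,attention_to_detail,TRUE
7,communication,TRUE
8,imagination,FALSE
9,attention_to_detail,TRUE
10,attention_switching,FALSE
11,social_skills,FALSE
12,attention_to_detail,TRUE
13,social_skills,TRUE
14,imagination,FALSE
15,social_skills,FALSE
16,attention_switching,TRUE
17,communication,FALSE
18,communication,TRUE
19,attention_to_detail,TRUE
20,imagination,TRUE
21,imagination,TRUE
22,social_skills,TRUE
23,attention_to_detail,TRUE
24,imagination,FALSE
25,attention_switching,FALSE
26,communication,TRUE
27,communication,FALSE
28,attention_to_detail,FALSE
29,attention_to_detail,FALSE
30,attention_to_detail,FALSE
31,communication,FALSE
32,attention_switching,FALSE
33,communication,TRUE
34,attention_switching,FALSE
35,communication,TRUE
36,social_skills,FALSE
37,attention_switching,FALSE
38,communication,FALSE
39,communication,TRUE
40,imagination,FALSE
41,imagination,TRUE
42,imagination,TRUE
43,attention_switching,TRUE
44,social_skills,FALSE
45,social_skills,TRUE
46,attention_switching,TRUE
47,social_skills,FALSE
48,social_skills,FALSE
49,attention_to_detail,FALSE
50,imagination,FALSE
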