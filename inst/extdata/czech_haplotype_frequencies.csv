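dqa1,dqb1,frequency,predisposing
DQA1*05,DQB1*02,0.092,TRUE
DQA1*02,DQB1*02,0.083,TRUE
DQA1*03,DQB1*03:02,0.069,TRUE
DQA1*05,DQB1*03:01,0.115,FALSE
DQA1*03,DQB1*03:03,0.040,FALSE
DQA1*01,DQB1*05:01,0.130,FALSE
DQA1*01,DQB1*06:02,0.130,FALSE
DQA1*01,DQB1*06:03,0.090,FALSE
DQA1*01,DQB1*05:03,0.050,FALSE
DQA1*04,DQB1*04:02,0.040,FALSE
DQA1*03,DQB1*03:01,0.050,FALSE
DQA1*02,DQB1*03:03,0.030,FALSE
DQA1*04,DQB1*03:01,0.030,FALSE
DQA1*01,DQB1*06:04,0.051,FALSE
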