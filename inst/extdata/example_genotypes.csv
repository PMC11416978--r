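sample_id,dqa1_1,dqa1_2,dqb1_1,dqb1_2
EX01,DQA1*05:01,DQA1*03:01,DQB1*02:01,DQB1*03:02
EX02,DQA1*05:05,DQA1*01:01,DQB1*03:01,DQB1*05:01
EX03,DQA1*01:01,DQA1*01:02,DQB1*05:01,DQB1*06:02
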