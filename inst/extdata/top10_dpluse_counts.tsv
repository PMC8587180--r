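16.3.1.1	Worrying about cancer with subjective symptoms	1661
16.2.1.1	Matters related to cancer screening	702
16.3.2.1	Concerns regarding suspicion of cancer (other)	494
12.2.4.1	Anxiety due to lack of knowledge about cancer	419
3.1.3.5	The received treatment (choice), whether it is correct	255
3.2.2.2	Worrying about the results and its trend	234
12.1.1.1	Anxiety about the possibility of recurrence or metastasis	225
9.1.2.2	Difficulty in asking questions or expressing concerns to the doctor	137
12.3.2.3	I can't stop thinking about cancer	111
9.1.1.1	Doctor's words and attitude	93
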