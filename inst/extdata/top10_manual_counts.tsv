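16.3.1.1	Worrying about cancer with subjective symptoms	160
16.2.1.1	Matters related to cancer screening	85
12.2.4.1	Anxiety due to lack of knowledge about cancer	42
16.3.2.1	Concerns regarding suspicion of cancer (other)	39
9.1.2.2	Difficulty in asking questions or expressing concerns to the doctor	17
3.2.2.2	Worrying about the results and their trends	17
12.1.1.1	Anxiety about the possibility of recurrence or metastasis	14
3.2.1.6	Concerns about undergoing tests (other)	11
3.1.1.1	Uncertainty about treatment options	10
3.2.2.3	Issues related to receiving tests (other)	9
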