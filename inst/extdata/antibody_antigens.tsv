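name	sequence	target_isoforms	ref_isoform	aa_start	aa_end
anti-FOR-1	SPPKIKENLSKSSSAYSTFSSAAEDSQDQVVICQQPQ	P2,P4	P2	191	227
anti-FOR-2	RRLSLEQAIEGLKLEGEKAVRQKSPQISPAASSNGSSKDLNGEGFCIPRPRLIVPVHTYARRRRTGNLKEQSSGGQE	P2,P4	P2	286	362
anti-FOR-3	WFDGFYWWGLQNCTLEPPIKPAVKSVVDTTNFDDYPPDPEGPPP	P1,P1a,P2,P3,P4,P5,P6,P7	NA	NA	NA
anti-FOR-4	HSSTTVDAPPRPADVDVATVPVATTAPPPQQPVSNLFYADYQKLQPAIIDRDWERDRDTDTDTRSEAKPPDIVEHIEPVEEQRQIHTQIQSPAEIQIQIPPTPPAPSIQIQIQQRYRRHSSAEDRNLNTRRNDSNITEALRKAASMQ	P1	P1	25	171
anti-FOR-5	QQELQLQQRYQQLQQLQAQTQGLYTSQGSPVLYHQPSPGSSQPVAIPGATCHSPTQLQPPNTL	P1,P1a	P1	278	340
anti-FOR-6	ISGCTPSGTGGSATPSPVGLVDPNFIVSNYVAASPQEECFIQIIQAKELKIQEMQRALQFKDNEIAELKSHLDKFQSVFPFSRGSAAGCAGTGGASGSGAGGSGGSGPGTATGATRKSGQNFQRQRALGISAEPQSESSLLL	P1,P1a,P3	P1	351	492
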