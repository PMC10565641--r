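>SYN0005
PVKDGSAQDTFWPRKNAAYMKDVSVCQYGLPTPVWSMYNCHLWTPVRKMPWGWMSQACNQMAYIPLTPMDTLVMGSSYMNKRWTWFDT
>orth01
PVKDGSAQDTFWPQKNAAYQDDVSVCQYGLPTPVWSMYNCHLWTPVRKCPWGWKTQACNQEAYIPLTPMDTLVMGSSYMNKRWTWFDV
>orth02
PVKDGSAGDAFWPRKNGAYMKDISVCQYGLPTPVWSMYNFHLWTPVRKMPWGWMSFACNQMAYIPLTPSDTLVMGSSWMNLRWTWNDM
>orth03
PVKDGSAQDTFWPRKNAAYMKDVSVCQYGLPTPVWSMINCHLWTPVRKYLWGWMSQACNQMAYIPLTTMDTRVMGSSYHNKRWWWFDT
>orth04
PVKDGWAQDTFWPRKNAAYMKDVSVCQYGLPTPVWSMYNCFLVTPVREMPWGPMSEACNQMAYIPLTPVDTLVMQSSYMNKRWTWFDT
>orth05
PVKDGSAQDTFWPRKNAAYMKDVSVCQYGLPTPVWSMYNCHLWTPVSKMPWGWMSQARNQWAYIPLTPMDTLVMKSSTMNKRWTWFDT
>orth06
PVKDGSAQDTFIPRKEAAYMKDVSVCQYGLPTPVWSMYNCHLWTPVRKMPWGWMSDSCNQMAYIPLTPMDTLVMGSSYMNKRWTWFDT
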