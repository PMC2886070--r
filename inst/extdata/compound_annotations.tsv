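compound	name	chain_class	alkenyl
3MTP	3-methylthiopropyl glucosinolate	C3	FALSE
4MTB	4-methylthiobutyl glucosinolate	C4	FALSE
3MSOP	3-methylsulfinylpropyl glucosinolate	C3	FALSE
4MSOB	4-methylsulfinylbutyl glucosinolate	C4	FALSE
allyl	2-propenyl glucosinolate	C3	TRUE
3-butenyl	3-butenyl glucosinolate	C4	TRUE
S-2OH3-butenyl	S-2-hydroxy-3-butenyl glucosinolate	C4	TRUE
6MSOH	6-methylsulfinylhexyl glucosinolate	long-chain	FALSE
7MTH	7-methylthioheptyl glucosinolate	long-chain	FALSE
7MSOH	7-methylsulfinylheptyl glucosinolate	long-chain	FALSE
8MSOO	8-methylsulfinyloctyl glucosinolate	long-chain	FALSE
1MOI3M	1-methoxy-indolyl-3-methyl glucosinolate	indolic	FALSE
4OHI3M	4-hydroxy-indolyl-3-methyl glucosinolate	indolic	FALSE
4MOI3M	4-methoxy-indolyl-3-methyl glucosinolate	indolic	FALSE
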