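name	formula	class
Guanidinosuccinic acid	C5H9N3O4	organic acid
Hippuric acid	C9H9NO3	organic acid
Biliverdin	C33H34N4O6	heme metabolite
Bilirubin	C33H36N4O6	heme metabolite
Oleic acid	C18H34O2	fatty acid
Stearic acid	C18H36O2	fatty acid
Arachidonic acid	C20H32O2	fatty acid
Docosahexaenoic acid	C22H32O2	fatty acid
Oleamide	C18H35NO	fatty amide
Sphingosine-1-phosphate	C18H38NO5P	sphingolipid
Sphinganine-1-phosphate	C18H40NO5P	sphingolipid
Decanoylcarnitine	C17H33NO4	acylcarnitine
Dodecanoylcarnitine	C19H37NO4	acylcarnitine
Tetradecenoylcarnitine	C21H39NO4	acylcarnitine
Palmitoylcarnitine	C23H45NO4	acylcarnitine
Linoleylcarnitine	C25H45NO4	acylcarnitine
Oleoylcarnitine	C25H47NO4	acylcarnitine
Stearoylcarnitine	C25H49NO4	acylcarnitine
LysoPC(16:1)	C24H48NO7P	lysoPC
LysoPC(16:0)	C24H50NO7P	lysoPC
LysoPC(18:2)	C26H50NO7P	lysoPC
LysoPC(18:1)	C26H52NO7P	lysoPC
LysoPC(18:0)	C26H54NO7P	lysoPC
LysoPC(20:4)	C28H50NO7P	lysoPC
LysoPC(20:3)	C28H52NO7P	lysoPC
LysoPC(22:6)	C30H50NO7P	lysoPC
LysoPE(16:0)	C21H44NO7P	lysoPE
LysoPE(18:2)	C23H44NO7P	lysoPE
LysoPE(18:1)	C23H46NO7P	lysoPE
LysoPE(18:0)	C23H48NO7P	lysoPE
LysoPE(20:4)	C25H44NO7P	lysoPE
LysoPE(22:6)	C27H44NO7P	lysoPE
LysoPE(22:5)	C27H46NO7P	lysoPE
PC(40:6)	C48H84NO8P	phosphatidylcholine
Carnitine	C7H15NO3	amino acid derivative
Choline	C5H13NO	amine
Creatinine	C4H7N3O	organic acid
Caffeine	C8H10N4O2	xenobiotic
Glucose	C6H12O6	sugar
Cholesterol	C27H46O	sterol
Cholic acid	C24H40O5	bile acid
Chenodeoxycholic acid	C24H40O4	bile acid
Tryptophan	C11H12N2O2	amino acid
Phenylalanine	C9H11NO2	amino acid
Uric acid	C5H4N4O3	purine metabolite
Alpha-tocopherol	C29H50O2	vitamin
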