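gene	chrom	start	end	convention
PLCB1	20	8130000	8950000	1-based-closed
PLCB2	15	40280000	40310000	1-based-closed
PLCB3	11	64250000	64280000	1-based-closed
PLCB4	20	9070000	9480000	1-based-closed
PLCG1	20	41140000	41200000	1-based-closed
PLCG2	16	81780000	81970000	1-based-closed
PLCD1	3	38005000	38028000	1-based-closed
PLCE1	10	94000000	94340000	1-based-closed
ITPR1	3	4490000	4850000	1-based-closed
ITPR2	12	26330000	26830000	1-based-closed
ITPR3	6	33620000	33700000	1-based-closed
PRKCA	17	66300000	66810000	1-based-closed
PRKCB	16	23840000	24230000	1-based-closed
PRKCE	2	45650000	46190000	1-based-closed
PRKCH	14	61420000	61660000	1-based-closed
PRKCQ	10	6420000	6580000	1-based-closed
DGKA	12	55930000	55960000	1-based-closed
DGKB	7	14140000	14900000	1-based-closed
DGKD	2	233350000	233470000	1-based-closed
DGKG	3	185780000	186000000	1-based-closed
DGKH	13	42020000	42250000	1-based-closed
DGKQ	4	955000	985000	1-based-closed
DGKZ	11	46332000	46390000	1-based-closed
DAGLA	11	61680000	61750000	1-based-closed
DAGLB	7	6400000	6470000	1-based-closed
MGLL	3	127690000	127830000	1-based-closed
RASGRP2	11	64730000	64750000	1-based-closed
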