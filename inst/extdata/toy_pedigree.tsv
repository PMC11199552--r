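individual_id	family_id	role	sex	birth_year	months_enrolled	location_id
f01_1	f01	father	M	1968	84	locA
f01_2	f01	mother	F	1970	84	locA
f01_3	f01	child	F	1994	84	locA
f01_4	f01	child	M	1996	84	locA
f02_1	f02	father	M	1962	96	locB
f02_2	f02	mother	F	1965	96	locB
f02_3	f02	child	M	1990	96	locB
f03_1	f03	father	M	1971	72	locC
f03_2	f03	mother	F	1973	72	locC
f03_3	f03	child	F	1999	72	locC
f03_4	f03	child	F	2001	72	locC
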