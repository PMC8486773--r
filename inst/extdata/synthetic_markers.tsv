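accession	compartment
SYN0001	mitochondria
SYN0002	mitochondria
SYN0003	mitochondria
SYN0004	mitochondria
SYN0005	mitochondria
SYN0006	ER
SYN0007	ER
SYN0008	ER
SYN0009	ER
SYN0010	ER
SYN0011	Golgi apparatus
SYN0012	Golgi apparatus
SYN0013	Golgi apparatus
SYN0014	Golgi apparatus
SYN0015	Golgi apparatus
SYN0016	lysosome
SYN0017	lysosome
SYN0018	lysosome
SYN0019	lysosome
SYN0020	lysosome
SYN0021	peroxisome
SYN0022	peroxisome
SYN0023	peroxisome
SYN0024	peroxisome
SYN0025	peroxisome
SYN0026	PM
SYN0027	PM
SYN0028	PM
SYN0029	PM
SYN0030	PM
SYN0031	nucleus
SYN0032	nucleus
SYN0033	nucleus
SYN0034	nucleus
SYN0035	nucleus
SYN0036	nucleolus
SYN0037	nucleolus
SYN0038	nucleolus
SYN0039	nucleolus
SYN0040	nucleolus
SYN0041	chromatin
SYN0042	chromatin
SYN0043	chromatin
SYN0044	chromatin
SYN0045	chromatin
SYN0046	ribosome
SYN0047	ribosome
SYN0048	ribosome
SYN0049	ribosome
SYN0050	ribosome
SYN0051	cytosol
SYN0052	cytosol
SYN0053	cytosol
SYN0054	cytosol
SYN0055	cytosol
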