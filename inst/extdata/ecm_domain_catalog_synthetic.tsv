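accession	name
IPRX00001	synthetic ECM domain 01
IPRX00002	synthetic ECM domain 02
IPRX00003	synthetic ECM domain 03
IPRX00004	synthetic ECM domain 04
IPRX00005	synthetic ECM domain 05
IPRX00006	synthetic ECM domain 06
IPRX00007	synthetic ECM domain 07
IPRX00008	synthetic ECM domain 08
IPRX00009	synthetic ECM domain 09
IPRX00010	synthetic ECM domain 10
IPRX00011	synthetic ECM domain 11
IPRX00012	synthetic ECM domain 12
IPRX00013	synthetic ECM domain 13
IPRX00014	synthetic ECM domain 14
IPRX00015	synthetic ECM domain 15
IPRX00016	synthetic ECM domain 16
IPRX00017	synthetic ECM domain 17
IPRX00018	synthetic ECM domain 18
IPRX00019	synthetic ECM domain 19
IPRX00020	synthetic ECM domain 20
IPRX00021	synthetic ECM domain 21
IPRX00022	synthetic ECM domain 22
IPRX00023	synthetic ECM domain 23
IPRX00024	synthetic ECM domain 24
IPRX00025	synthetic ECM domain 25
IPRX00026	synthetic ECM domain 26
IPRX00027	synthetic ECM domain 27
IPRX00028	synthetic ECM domain 28
IPRX00029	synthetic ECM domain 29
IPRX00030	synthetic ECM domain 30
IPRX00031	synthetic ECM domain 31
IPRX00032	synthetic ECM domain 32
IPRX00033	synthetic ECM domain 33
IPRX00034	synthetic ECM domain 34
IPRX00035	synthetic ECM domain 35
IPRX00036	synthetic ECM domain 36
IPRX00037	synthetic ECM domain 37
IPRX00038	synthetic ECM domain 38
IPRX00039	synthetic ECM domain 39
IPRX00040	synthetic ECM domain 40
IPRX00041	synthetic ECM domain 41
IPRX00042	synthetic ECM domain 42
IPRX00043	synthetic ECM domain 43
IPRX00044	synthetic ECM domain 44
IPRX00045	synthetic ECM domain 45
IPRX00046	synthetic ECM domain 46
IPRX00047	synthetic ECM domain 47
IPRX00048	synthetic ECM domain 48
IPRX00049	synthetic ECM domain 49
IPRX00050	synthetic ECM domain 50
IPRX00051	synthetic ECM domain 51
IPRX00052	synthetic ECM domain 52
IPRX00053	synthetic ECM domain 53
IPRX00054	synthetic ECM domain 54
IPRX00055	synthetic ECM domain 55
IPRX00056	synthetic ECM domain 56
IPRX00057	synthetic ECM domain 57
IPRX00058	synthetic ECM domain 58
IPRX00059	synthetic ECM domain 59
IPRX00060	synthetic ECM domain 60
IPRX00061	synthetic ECM domain 61
IPRX00062	synthetic ECM domain 62
IPRX00063	synthetic ECM domain 63
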