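pcg_00002
pcg_00035
pcg_00036
pcg_00038
pcg_00039
pcg_00040
pcg_00041
pcg_00043
pcg_00044
pcg_00046
pcg_00047
pcg_00056
pcg_00095
pcg_00096
pcg_00097
pcg_00068
pcg_00100
pcg_00072
pcg_00074
pcg_00077
pcg_00082
pcg_00086
pcg_00087
pcg_38909
pcg_00001
pcg_00033
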