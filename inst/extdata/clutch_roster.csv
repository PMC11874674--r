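clutch_id,year,host_species,n_embryos
19.GP01,2019,Gnathochromis pfefferi,4
19.SD01,2019,Simochromis diagramma,3
19.GP02,2019,Gnathochromis pfefferi,14
19.SD02,2019,Simochromis diagramma,5
19.SH01,2019,Shuja horei,3
19.SD03,2019,Simochromis diagramma,3
19.SD04,2019,Simochromis diagramma,5
19.SD05,2019,Simochromis diagramma,8
22.SH01,2022,Shuja horei,8
22.SH02,2022,Shuja horei,7
22.SH03,2022,Shuja horei,7
22.SH04,2022,Shuja horei,5
22.SH05,2022,Shuja horei,6
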