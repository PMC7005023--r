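lineage_id	taxon_name	rank	genus	group	sensitive
L01	Tubifex sp. 1	species	Tubifex	tubificinae_nohair	FALSE
L02	Spirosperma sp. 2	species	Spirosperma	tubificinae_hair	TRUE
L03	Nais sp. 3	species	Nais	naidinae	FALSE
L04	Enchytraeus sp. 4	species	Enchytraeus	enchytraeidae	TRUE
L05	Lumbriculus sp. 5	species	Lumbriculus	lumbriculidae	TRUE
L06	Pristina sp. 6	species	Pristina	pristininae	TRUE
L07	Limnodrilus sp. 7	species	Limnodrilus	tubificinae_nohair	FALSE
L08	Psammoryctides sp. 8	species	Psammoryctides	tubificinae_hair	FALSE
L09	Uncinais sp. 9	species	Uncinais	naidinae	FALSE
L01b	Tubifex sp. 1	species	Tubifex	tubificinae_nohair	FALSE
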