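genome_id	taxonomy
tax_alpha	Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacter;Pelagibacter_synthA
tax_gamma	Bacteria;Proteobacteria;Gammaproteobacteria;SAR86;SAR86_synthA
tax_bacter	Bacteria;Bacteroidetes;Flavobacteriia;Flavobacterium;Flavobacterium_synthA
tax_cyano	Bacteria;Cyanobacteria;Cyanophyceae;Synechococcus;Synechococcus_synthA
tax_actino	Bacteria;Actinobacteria;Acidimicrobiia;Actinomarina;Actinomarina_synthA
tax_verruco	Bacteria;Verrucomicrobia;Verrucomicrobiae;Puniceicoccus;Puniceicoccus_synthA
tax_marini	Bacteria;Marinimicrobia;Marinimicrobia_cls;Marinimicrobia_gen;Marinimicrobia_synthA
tax_acido	Bacteria;Acidobacteria;Acidobacteriia;Acidobacterium;Acidobacterium_synthA
tax_plancto	Bacteria;Planctomycetes;Planctomycetia;Planctomyces;Planctomyces_synthA
tax_chloro	Bacteria;Chloroflexi;Anaerolineae;Anaerolinea;Anaerolinea_synthA
tax_eury1	Archaea;Euryarchaeota;MGII;MGII_gen;MGII_synthA
tax_eury2	Archaea;Euryarchaeota;MGIII;MGIII_gen;MGIII_synthA
tax_thaum1	Archaea;Thaumarchaeota;MGI;Nitrosopelagicus;Nitrosopelagicus_synthA
tax_thaum2	Archaea;Thaumarchaeota;MGI;Nitrosopumilus;Nitrosopumilus_synthA
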