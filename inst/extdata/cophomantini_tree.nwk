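((Myersiohyla_spp,(((Hyloscirtus_alytolylax,Hyloscirtus_palmeri)Hyloscirtus_bogotensis_group,(Hyloscirtus_armatus,Hyloscirtus_larinopygion)Hyloscirtus_armatus_larinopygion_clade)Hyloscirtus,((Bokermannohyla_spp,Bokermannohyla_alvarengai,Bokermannohyla_ibitiguara)Bokermannohyla,(((Aplastodiscus_cochranae,Aplastodiscus_perviridis)Aplastodiscus_perviridis_group,(Aplastodiscus_arildae,Aplastodiscus_ehrhardti,(Aplastodiscus_albofrenatus,Aplastodiscus_eugenioi))Aplastodiscus_albofrenatus_group,(Aplastodiscus_albosignatus,Aplastodiscus_callipygius,Aplastodiscus_leucopygius)Aplastodiscus_albosignatus_group)Aplastodiscus,(((Boana_albopunctata,Boana_cf_alfaroi,Boana_leucocheila,Boana_multifasciata)Boana_albopunctata_22_clade,Boana_almendarizae,Boana_calcarata,Boana_cf_lanciformis,Boana_fasciata,Boana_heilprini,Boana_raniceps)Boana_albopunctata_group,Boana_faber,Boana_pellucens,((Boana_caingua,Boana_prasina,Boana_pulchella)Boana_caingua_prasina_pulchella_clade,(Boana_cipoensis,(Boana_curupi,Boana_joaquini,Boana_semiguttata,Boana_stellae)Boana_semiguttata_clade)Boana_polytaenia_semiguttata_clade,Boana_albonigra,Boana_bischoffi,Boana_cordobae,Boana_guentheri,Boana_marginata,Boana_marianitae,Boana_riojana)Boana_pulchella_group,(Boana_cinerascens,Boana_punctata)Boana_punctata_group,(Boana_boans,Boana_cf_semilineata,Boana_geographica,Boana_pombali,Boana_semilineata,Boana_wavrini)Boana_semilineata_group)Boana)))Cophomantini,(Dendropsophini_modal,Hylini_modal,Lophyohylini_modal))Hylinae,(Pelodryadinae_modal,Phyllomedusinae_modal));
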