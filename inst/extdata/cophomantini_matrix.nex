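#NEXUS

[KARYEVO-LEGEND char=x 0=9 1=10 2=11 3=12 4=13]
[KARYEVO-LEGEND char=nor_position 0=1 1=2 2=4a 3=4b 4=4c 5=6 6=7 7=8 8=11 9=12]

BEGIN DATA;
  DIMENSIONS NTAX=57 NCHAR=2;
  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS="0123456789";
  MATRIX
    Phyllomedusinae_modal       4?
    Pelodryadinae_modal         4?
    Dendropsophini_modal        38
    Hylini_modal                38
    Lophyohylini_modal          38
    Myersiohyla_spp             ??
    Hyloscirtus_alytolylax      13
    Hyloscirtus_palmeri         34
    Hyloscirtus_armatus         3?
    Hyloscirtus_larinopygion    30
    Bokermannohyla_spp          38
    Bokermannohyla_alvarengai   32
    Bokermannohyla_ibitiguara   30
    Aplastodiscus_cochranae     38
    Aplastodiscus_perviridis    38
    Aplastodiscus_arildae       28
    Aplastodiscus_ehrhardti     25
    Aplastodiscus_albofrenatus  25
    Aplastodiscus_eugenioi      25
    Aplastodiscus_albosignatus  18
    Aplastodiscus_callipygius   ?8
    Aplastodiscus_leucopygius   08
    Boana_albopunctata          27
    Boana_cf_alfaroi            27
    Boana_leucocheila           27
    Boana_multifasciata         27
    Boana_almendarizae          39
    Boana_calcarata             3?
    Boana_cf_lanciformis        38
    Boana_fasciata              3?
    Boana_heilprini             3?
    Boana_raniceps              38
    Boana_faber                 38
    Boana_pellucens             38
    Boana_albonigra             38
    Boana_bischoffi             38
    Boana_caingua               39
    Boana_cipoensis             30
    Boana_cordobae              38
    Boana_curupi                30
    Boana_guentheri             ?8
    Boana_joaquini              ?0
    Boana_marginata             ?8
    Boana_marianitae            38
    Boana_prasina               ?{89}
    Boana_pulchella             39
    Boana_riojana               38
    Boana_semiguttata           ?0
    Boana_stellae               30
    Boana_cinerascens           38
    Boana_punctata              38
    Boana_boans                 36
    Boana_cf_semilineata        36
    Boana_geographica           ?0
    Boana_pombali               ?6
    Boana_semilineata           ?6
    Boana_wavrini               38
  ;
END;
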