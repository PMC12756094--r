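study_id	run_id	treated	library_layout
PRJNA307652	PRJNA307652_C1	FALSE	PE
PRJNA307652	PRJNA307652_C2	FALSE	PE
PRJNA307652	PRJNA307652_C3	FALSE	PE
PRJNA307652	PRJNA307652_C4	FALSE	PE
PRJNA307652	PRJNA307652_C5	FALSE	PE
PRJNA307652	PRJNA307652_C6	FALSE	PE
PRJNA307652	PRJNA307652_C7	FALSE	PE
PRJNA307652	PRJNA307652_C8	FALSE	PE
PRJNA307652	PRJNA307652_T1	TRUE	PE
PRJNA307652	PRJNA307652_T2	TRUE	PE
PRJNA575504	PRJNA575504_C1	FALSE	PE
PRJNA575504	PRJNA575504_C2	FALSE	PE
PRJNA575504	PRJNA575504_C3	FALSE	PE
PRJNA575504	PRJNA575504_T1	TRUE	PE
PRJNA578611	PRJNA578611_C1	FALSE	PE
PRJNA578611	PRJNA578611_C2	FALSE	PE
PRJNA578611	PRJNA578611_T1	TRUE	PE
PRJNA578611	PRJNA578611_T2	TRUE	PE
PRJNA777606	PRJNA777606_C1	FALSE	PE
PRJNA777606	PRJNA777606_C2	FALSE	PE
PRJNA777606	PRJNA777606_T1	TRUE	PE
PRJNA847413	PRJNA847413_C1	FALSE	PE
PRJNA847413	PRJNA847413_C2	FALSE	PE
PRJNA847413	PRJNA847413_C3	FALSE	PE
PRJNA847413	PRJNA847413_C4	FALSE	PE
PRJEB48614	PRJEB48614_C1	FALSE	PE
PRJEB48614	PRJEB48614_C2	FALSE	PE
PRJEB48614	PRJEB48614_C3	FALSE	PE
PRJEB48614	PRJEB48614_T1	TRUE	PE
PRJNA667281	PRJNA667281_C1	FALSE	PE
PRJNA667281	PRJNA667281_C2	FALSE	PE
PRJNA667281	PRJNA667281_C3	FALSE	PE
PRJNA667281	PRJNA667281_T1	TRUE	PE
PRJNA667281	PRJNA667281_T2	TRUE	PE
PRJNA896725	PRJNA896725_C1	FALSE	PE
PRJNA896725	PRJNA896725_C2	FALSE	PE
PRJNA896725	PRJNA896725_C3	FALSE	PE
PRJNA896725	PRJNA896725_C4	FALSE	PE
PRJNA896725	PRJNA896725_C5	FALSE	PE
PRJNA896725	PRJNA896725_T1	TRUE	PE
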