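case_id,mc,amf_count,multipolar_count,multinucleated_count,bizarre_nuclei_count,karyomegaly,followup_months,died,death_tumor_related
case_01,8,4,2,0,0,FALSE,2,TRUE,TRUE
case_02,100,15,4,0,0,FALSE,3,TRUE,TRUE
case_03,60,10,3,0,0,FALSE,4,TRUE,TRUE
case_04,50,8,2,0,0,FALSE,5,TRUE,TRUE
case_05,40,6,1,0,0,FALSE,6,TRUE,TRUE
case_06,12,5,1,0,0,FALSE,7,TRUE,TRUE
case_07,10,4,1,0,0,FALSE,8,TRUE,TRUE
case_08,9,3,0,0,0,FALSE,9,TRUE,TRUE
case_09,29,4,0,0,0,FALSE,9,TRUE,TRUE
case_10,7,3,0,0,0,FALSE,10,TRUE,TRUE
case_11,4,1,0,0,0,FALSE,14,TRUE,TRUE
case_12,2,0,0,0,0,FALSE,20,TRUE,TRUE
case_13,3,1,0,0,0,TRUE,30,TRUE,TRUE
case_14,6,1,0,0,0,FALSE,24,FALSE,FALSE
case_15,15,1,0,0,0,FALSE,30,FALSE,FALSE
case_16,20,1,0,0,0,FALSE,36,FALSE,FALSE
case_17,25,0,0,0,0,FALSE,42,FALSE,FALSE
case_18,12,0,0,0,0,FALSE,48,FALSE,FALSE
case_19,27,3,1,0,0,FALSE,54,FALSE,FALSE
case_20,5,0,0,0,0,TRUE,26,FALSE,FALSE
case_21,5,0,0,3,0,FALSE,33,FALSE,FALSE
case_22,1,1,0,0,0,FALSE,13,FALSE,FALSE
case_23,1,1,0,0,0,FALSE,14,FALSE,FALSE
case_24,1,1,0,0,0,FALSE,15,FALSE,FALSE
case_25,1,1,0,0,0,FALSE,16,FALSE,FALSE
case_26,1,1,0,0,0,FALSE,17,FALSE,FALSE
case_27,2,1,0,0,0,FALSE,18,FALSE,FALSE
case_28,2,1,0,0,0,FALSE,19,FALSE,FALSE
case_29,2,1,0,0,0,FALSE,20,FALSE,FALSE
case_30,2,1,0,0,0,FALSE,21,FALSE,FALSE
case_31,0,0,0,0,0,FALSE,19,FALSE,FALSE
case_32,0,0,0,0,0,FALSE,26,FALSE,FALSE
case_33,0,0,0,0,0,FALSE,3,TRUE,FALSE
case_34,0,0,0,0,0,FALSE,40,FALSE,FALSE
case_35,0,0,0,0,0,FALSE,47,FALSE,FALSE
case_36,0,0,0,0,0,FALSE,54,FALSE,FALSE
case_37,1,0,0,0,0,FALSE,13,FALSE,FALSE
case_38,1,0,0,0,0,FALSE,20,FALSE,FALSE
case_39,1,0,0,0,0,FALSE,7,TRUE,FALSE
case_40,1,0,0,0,0,FALSE,34,FALSE,FALSE
case_41,1,0,0,0,0,FALSE,41,FALSE,FALSE
case_42,1,0,0,0,0,FALSE,48,FALSE,FALSE
case_43,1,0,0,0,0,FALSE,55,FALSE,FALSE
case_44,1,0,0,0,0,FALSE,14,FALSE,FALSE
case_45,1,0,0,0,0,FALSE,10,TRUE,FALSE
case_46,1,0,0,0,0,FALSE,28,FALSE,FALSE
case_47,2,0,0,0,0,FALSE,35,FALSE,FALSE
case_48,2,0,0,0,0,FALSE,42,FALSE,FALSE
case_49,2,0,0,0,0,FALSE,49,FALSE,FALSE
case_50,2,0,0,0,0,FALSE,56,FALSE,FALSE
case_51,2,0,0,0,0,FALSE,15,TRUE,FALSE
case_52,2,0,0,0,0,FALSE,22,FALSE,FALSE
case_53,2,0,0,0,0,FALSE,29,FALSE,FALSE
case_54,2,0,0,0,0,FALSE,36,FALSE,FALSE
case_55,2,0,0,0,0,FALSE,43,FALSE,FALSE
case_56,2,0,0,0,0,FALSE,50,FALSE,FALSE
case_57,2,0,0,0,0,FALSE,18,TRUE,FALSE
case_58,2,0,0,0,0,FALSE,16,FALSE,FALSE
case_59,3,1,0,0,0,FALSE,23,FALSE,FALSE
case_60,3,1,0,0,0,FALSE,30,FALSE,FALSE
case_61,3,1,0,0,0,FALSE,37,FALSE,FALSE
case_62,3,1,0,0,0,FALSE,44,FALSE,FALSE
case_63,3,1,0,0,0,FALSE,22,TRUE,FALSE
case_64,3,1,0,0,0,FALSE,58,FALSE,FALSE
case_65,3,1,0,0,0,FALSE,17,FALSE,FALSE
case_66,3,1,0,0,0,FALSE,24,FALSE,FALSE
case_67,3,0,0,0,0,FALSE,31,FALSE,FALSE
case_68,3,0,0,0,0,FALSE,38,FALSE,FALSE
case_69,3,0,0,0,0,FALSE,26,TRUE,FALSE
case_70,3,0,0,0,0,FALSE,52,FALSE,FALSE
case_71,4,1,0,0,0,FALSE,59,FALSE,FALSE
case_72,4,1,0,0,0,FALSE,18,FALSE,FALSE
case_73,4,1,0,0,0,FALSE,25,FALSE,FALSE
case_74,4,1,0,0,0,FALSE,32,FALSE,FALSE
case_75,4,1,0,0,0,FALSE,31,TRUE,FALSE
case_76,4,1,0,0,0,FALSE,46,FALSE,FALSE
case_77,4,1,0,0,0,FALSE,53,FALSE,FALSE
case_78,4,1,0,0,0,FALSE,12,FALSE,FALSE
case_79,4,0,0,0,0,FALSE,19,FALSE,FALSE
case_80,4,0,0,0,0,FALSE,26,FALSE,FALSE
case_81,4,0,0,0,0,FALSE,38,TRUE,FALSE
case_82,4,0,0,0,0,FALSE,40,FALSE,FALSE
case_83,5,1,0,0,0,FALSE,47,FALSE,FALSE
case_84,5,1,0,0,0,FALSE,54,FALSE,FALSE
case_85,5,1,0,0,0,FALSE,13,FALSE,FALSE
case_86,5,1,0,0,0,FALSE,20,FALSE,FALSE
case_87,5,1,0,0,0,FALSE,44,TRUE,FALSE
case_88,5,1,0,0,0,FALSE,34,FALSE,FALSE
case_89,5,1,0,0,0,FALSE,41,FALSE,FALSE
case_90,5,1,0,0,0,FALSE,48,FALSE,FALSE
case_91,5,0,0,0,0,FALSE,55,FALSE,FALSE
case_92,5,0,0,0,0,FALSE,14,FALSE,FALSE
case_93,5,0,0,0,0,FALSE,50,TRUE,FALSE
case_94,5,0,0,0,0,FALSE,28,FALSE,FALSE
case_95,5,0,0,0,0,FALSE,35,FALSE,FALSE
case_96,5,0,0,0,0,FALSE,42,FALSE,FALSE
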