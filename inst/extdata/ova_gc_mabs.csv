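clonotype,mab_id,germline_mab,vh_v_call,vk_v_call,vh_cdr,vh_fw,vk_cdr,vk_fw,elisa_threshold_ng,ova_af647_asinh
c179,germline,TRUE,IGHV1-42*01,IGKV4-80*01,0,0,0,0,>1000,NA
c179,p7.BC76,FALSE,IGHV1-42*01,IGKV4-80*01,1,0,1,0,19.03,2.14
c179,p7.BC41,FALSE,IGHV1-42*01,IGKV4-80*01,0,1,2,1,>1000,0.06
c179,p7.BC49,FALSE,IGHV1-42*01,IGKV4-80*01,0,1,0,0,0.27,1.86
c179,p8.BC75,FALSE,IGHV1-42*01,IGKV4-80*01,1,0,1,0,4.85,1.53
c179,p8.BC46,FALSE,IGHV1-42*01,IGKV4-80*01,0,0,0,0,3.86,1.46
c248,germline,TRUE,IGHV1-26*01,IGKV4-61*01,0,0,0,0,>1000,NA
c248,p9.BC45,FALSE,IGHV1-26*01,IGKV4-61*01,2,3,0,0,>1000,0.03
c248,p9.BC76,FALSE,IGHV1-26*01,IGKV4-61*01,2,1,0,0,14.94,0.04
c248,p9.BC37,FALSE,IGHV1-26*01,IGKV4-61*01,2,1,0,0,615.18,0.44
c248,p9.BC61,FALSE,IGHV1-26*01,IGKV4-61*01,0,1,0,0,539,0.21
c248,p9.BC64,FALSE,IGHV1-26*01,IGKV4-61*01,0,0,0,0,412,0.60
c127,germline,TRUE,IGHV1-64*01,IGKV1-99*01,0,0,0,0,0.75,NA
c127,p9.BC16,FALSE,IGHV1-64*01,IGKV1-99*01,1,1,0,2,219,1.35
c127,p9.BC78,FALSE,IGHV1-64*01,IGKV1-99*01,1,0,0,0,502,0.27
c127,p9.BC41,FALSE,IGHV1-64*01,IGKV1-99*01,1,1,0,1,1.74,1.89
c127,p10.BC3,FALSE,IGHV1-64*01,IGKV1-99*01,0,0,0,0,1.6,1.57
c127,p9.BC1,FALSE,IGHV1-64*01,IGKV1-99*01,1,0,0,0,129,0.68
c127,p9.BC18,FALSE,IGHV1-64*01,IGKV1-99*01,0,0,0,0,3.2,1.27
c127,p10.BC50,FALSE,IGHV1-64*01,IGKV1-99*01,1,1,0,0,8.9,2.06
c87,germline,TRUE,IGHV1-63*01,IGKV1-117*01,0,0,0,0,>1000,NA
c87,p8.BC50,FALSE,IGHV1-63*01,IGKV1-117*01,2,5,2,3,0.8,1.93
c87,p7.BC31,FALSE,IGHV1-63*01,IGKV1-117*01,2,1,0,1,336,0.48
c87,p7.BC19,FALSE,IGHV1-63*01,IGKV1-117*01,1,2,0,2,10.8,0.24
c87,p7.BC16,FALSE,IGHV1-63*01,IGKV1-117*01,1,3,1,0,1.94,1.43
c87,p8.BC83,FALSE,IGHV1-63*01,IGKV1-117*01,2,1,1,1,1.73,1.41
c87,p7.BC1,FALSE,IGHV1-63*01,IGKV1-117*01,0,0,1,0,0.74,1.64
c87,p7.BC27,FALSE,IGHV1-63*01,IGKV1-117*01,0,0,0,0,0.42,1.09
c184,germline,TRUE,IGHV1-81*01,IGKV13-84*01,0,0,0,0,>1000,NA
c184,p10.BC30,FALSE,IGHV1-81*01,IGKV13-84*01,1,1,0,4,14.6,0.13
c184,p9.BC6,FALSE,IGHV1-81*01,IGKV13-84*01,2,0,2,2,>1000,0.03
c184,p10.BC57,FALSE,IGHV1-81*01,IGKV13-84*01,0,0,0,0,352,1.47
c184,p9.BC75,FALSE,IGHV1-81*01,IGKV13-84*01,1,1,0,0,451,0.05
c184,p10.BC74,FALSE,IGHV1-81*01,IGKV13-84*01,1,0,0,4,24.8,0.33
c184,p10.BC38,FALSE,IGHV1-81*01,IGKV13-84*01,1,1,0,0,280,0.94
c184,p9.BC25,FALSE,IGHV1-81*01,IGKV13-84*01,1,2,0,0,>1000,0.00
c184,p9.BC40,FALSE,IGHV1-81*01,IGKV13-84*01,2,0,0,0,17,0.31
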