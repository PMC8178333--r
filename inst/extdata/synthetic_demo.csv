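# synthetic demo specimen (generateClustered, seed 8)
specimen_id,hook_id,morphotype,landmark_index,x,y,z
synthetic_seed8,1,G1,1,-2.002846891,-5.587283748,-3.479422018
synthetic_seed8,1,G1,2,-2.002846891,-7.587283748,-3.479422018
synthetic_seed8,1,G1,3,-4.002846891,-5.587283748,-3.479422018
synthetic_seed8,1,G1,4,-4.002846891,-7.587283748,-3.479422018
synthetic_seed8,2,G1,1,-0.620024834,-5.199052241,-3.440307053
synthetic_seed8,2,G1,2,-0.620024834,-7.199052241,-3.440307053
synthetic_seed8,2,G1,3,-2.620024834,-5.199052241,-3.440307053
synthetic_seed8,2,G1,4,-2.620024834,-7.199052241,-3.440307053
synthetic_seed8,3,G1,1,1.006595687,-4.914863745,-2.687958634
synthetic_seed8,3,G1,2,1.006595687,-6.914863745,-2.687958634
synthetic_seed8,3,G1,3,-0.993404313,-4.914863745,-2.687958634
synthetic_seed8,3,G1,4,-0.993404313,-6.914863745,-2.687958634
synthetic_seed8,4,G1,1,3.022830214,-4.919384611,-2.765150703
synthetic_seed8,4,G1,2,3.022830214,-6.919384611,-2.765150703
synthetic_seed8,4,G1,3,1.022830214,-4.919384611,-2.765150703
synthetic_seed8,4,G1,4,1.022830214,-6.919384611,-2.765150703
synthetic_seed8,5,G1,1,3.667847752,-5.192031422,-3.143128926
synthetic_seed8,5,G1,2,3.667847752,-7.192031422,-3.143128926
synthetic_seed8,5,G1,3,1.667847752,-5.192031422,-3.143128926
synthetic_seed8,5,G1,4,1.667847752,-7.192031422,-3.143128926
synthetic_seed8,6,G4,1,-1.568146845,-2.676014620,-2.971792608
synthetic_seed8,6,G4,2,-1.568146845,-4.676014620,-2.971792608
synthetic_seed8,6,G4,3,-3.568146845,-2.676014620,-2.971792608
synthetic_seed8,6,G4,4,-3.568146845,-4.676014620,-2.971792608
synthetic_seed8,7,G4,1,0.835348396,-3.109543902,-2.820306193
synthetic_seed8,7,G4,2,0.835348396,-5.109543902,-2.820306193
synthetic_seed8,7,G4,3,-1.164651604,-3.109543902,-2.820306193
synthetic_seed8,7,G4,4,-1.164651604,-5.109543902,-2.820306193
synthetic_seed8,8,G4,1,1.930812023,-2.823190383,-3.869189391
synthetic_seed8,8,G4,2,1.930812023,-4.823190383,-3.869189391
synthetic_seed8,8,G4,3,-0.069187977,-2.823190383,-3.869189391
synthetic_seed8,8,G4,4,-0.069187977,-4.823190383,-3.869189391
synthetic_seed8,9,G4,1,2.643817156,-3.028828784,-2.824890992
synthetic_seed8,9,G4,2,2.643817156,-5.028828784,-2.824890992
synthetic_seed8,9,G4,3,0.643817156,-3.028828784,-2.824890992
synthetic_seed8,9,G4,4,0.643817156,-5.028828784,-2.824890992
synthetic_seed8,10,G4,1,5.202002663,-2.708547673,-2.287174989
synthetic_seed8,10,G4,2,5.202002663,-4.708547673,-2.287174989
synthetic_seed8,10,G4,3,3.202002663,-2.708547673,-2.287174989
synthetic_seed8,10,G4,4,3.202002663,-4.708547673,-2.287174989
synthetic_seed8,11,G2,1,-1.710886673,5.173540683,2.806121382
synthetic_seed8,11,G2,2,-1.710886673,3.173540683,2.806121382
synthetic_seed8,11,G2,3,-3.710886673,5.173540683,2.806121382
synthetic_seed8,11,G2,4,-3.710886673,3.173540683,2.806121382
synthetic_seed8,12,G2,1,-0.966167424,4.766847949,3.072920694
synthetic_seed8,12,G2,2,-0.966167424,2.766847949,3.072920694
synthetic_seed8,12,G2,3,-2.966167424,4.766847949,3.072920694
synthetic_seed8,12,G2,4,-2.966167424,2.766847949,3.072920694
synthetic_seed8,13,G2,1,0.767907286,4.819747365,2.763152037
synthetic_seed8,13,G2,2,0.767907286,2.819747365,2.763152037
synthetic_seed8,13,G2,3,-1.232092714,4.819747365,2.763152037
synthetic_seed8,13,G2,4,-1.232092714,2.819747365,2.763152037
synthetic_seed8,14,G2,1,2.878233387,4.550204177,2.671890170
synthetic_seed8,14,G2,2,2.878233387,2.550204177,2.671890170
synthetic_seed8,14,G2,3,0.878233387,4.550204177,2.671890170
synthetic_seed8,14,G2,4,0.878233387,2.550204177,2.671890170
synthetic_seed8,15,G2,1,4.128536734,5.226249027,3.613382209
synthetic_seed8,15,G2,2,4.128536734,3.226249027,3.613382209
synthetic_seed8,15,G2,3,2.128536734,5.226249027,3.613382209
synthetic_seed8,15,G2,4,2.128536734,3.226249027,3.613382209
synthetic_seed8,16,G5,1,-0.996624939,7.167188298,2.495599899
synthetic_seed8,16,G5,2,-0.996624939,5.167188298,2.495599899
synthetic_seed8,16,G5,3,-2.996624939,7.167188298,2.495599899
synthetic_seed8,16,G5,4,-2.996624939,5.167188298,2.495599899
synthetic_seed8,17,G5,1,0.040254834,7.028463144,3.364584939
synthetic_seed8,17,G5,2,0.040254834,5.028463144,3.364584939
synthetic_seed8,17,G5,3,-1.959745166,7.028463144,3.364584939
synthetic_seed8,17,G5,4,-1.959745166,5.028463144,3.364584939
synthetic_seed8,18,G5,1,1.730541317,6.465567575,2.971282945
synthetic_seed8,18,G5,2,1.730541317,4.465567575,2.971282945
synthetic_seed8,18,G5,3,-0.269458683,6.465567575,2.971282945
synthetic_seed8,18,G5,4,-0.269458683,4.465567575,2.971282945
synthetic_seed8,19,G5,1,3.391295094,6.667362276,2.714581660
synthetic_seed8,19,G5,2,3.391295094,4.667362276,2.714581660
synthetic_seed8,19,G5,3,1.391295094,6.667362276,2.714581660
synthetic_seed8,19,G5,4,1.391295094,4.667362276,2.714581660
synthetic_seed8,20,G5,1,4.859050187,6.919765665,3.180379647
synthetic_seed8,20,G5,2,4.859050187,4.919765665,3.180379647
synthetic_seed8,20,G5,3,2.859050187,6.919765665,3.180379647
synthetic_seed8,20,G5,4,2.859050187,4.919765665,3.180379647
synthetic_seed8,21,G3,1,-4.768952844,-1.086955493,-3.915409847
synthetic_seed8,21,G3,2,-4.768952844,-3.086955493,-3.915409847
synthetic_seed8,21,G3,3,-6.768952844,-1.086955493,-3.915409847
synthetic_seed8,21,G3,4,-6.768952844,-3.086955493,-3.915409847
synthetic_seed8,22,G3,1,-3.590915087,-1.755226916,-0.362328952
synthetic_seed8,22,G3,2,-3.590915087,-3.755226916,-0.362328952
synthetic_seed8,22,G3,3,-5.590915087,-1.755226916,-0.362328952
synthetic_seed8,22,G3,4,-5.590915087,-3.755226916,-0.362328952
synthetic_seed8,23,VSB,1,-5.042099822,1.821470247,-0.289111197
synthetic_seed8,23,VSB,2,-5.042099822,-0.178529753,-0.289111197
synthetic_seed8,23,VSB,3,-7.042099822,1.821470247,-0.289111197
synthetic_seed8,23,VSB,4,-7.042099822,-0.178529753,-0.289111197
synthetic_seed8,24,VSB,1,-4.867068207,0.530701392,0.141234831
synthetic_seed8,24,VSB,2,-4.867068207,-1.469298608,0.141234831
synthetic_seed8,24,VSB,3,-6.867068207,0.530701392,0.141234831
synthetic_seed8,24,VSB,4,-6.867068207,-1.469298608,0.141234831
synthetic_seed8,25,TRI,1,11.073939315,-14.853540180,9.749559965
synthetic_seed8,25,TRI,2,11.073939315,-16.853540180,9.749559965
synthetic_seed8,25,TRI,3,9.073939315,-14.853540180,9.749559965
synthetic_seed8,25,TRI,4,9.073939315,-16.853540180,9.749559965
synthetic_seed8,26,RND,1,3.485678468,-4.351930612,16.011019433
synthetic_seed8,26,RND,2,3.485678468,-6.351930612,16.011019433
synthetic_seed8,26,RND,3,1.485678468,-4.351930612,16.011019433
synthetic_seed8,26,RND,4,1.485678468,-6.351930612,16.011019433
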