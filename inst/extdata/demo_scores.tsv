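gene_id	score
g00001	0.0259577
g00002	2.43572
g00003	8.82374
g00004	1.2979
g00005	0.566862
g00006	0.263774
g00007	0.261091
g00008	1.61992
g00009	0.380682
g00010	0.516529
g00011	33.3291
g00012	0.174443
g00013	0.551936
g00014	3.69915
g00015	34.1116
g00016	2.50942
g00017	22.6323
g00018	17.2985
g00019	18.254
g00020	6.05295
g00021	0.383184
g00022	0.150174
g00023	1.14556
g00024	19.5013
g00025	9.0582
g00026	20.1046
g00027	3.71207
g00028	0.0555312
g00029	13.2599
g00030	0.217871
g00031	3.37982
g00032	0.271901
g00033	0.167825
g00034	2.31685
g00035	0.111239
g00036	0.0501058
g00037	0.112399
g00038	0.671946
g00039	0.695373
g00040	0.578908
g00041	0.0911468
g00042	0.0250055
g00043	26.6715
g00044	2.748
g00045	2.7008
g00046	1.9975
g00047	1.9138
g00048	0.345457
g00049	0.213718
g00050	1.52518
g00051	0.00594602
g00052	0.132719
g00053	1.24123
g00054	0.358341
g00055	0.391012
g00056	0.407287
g00057	0.0445314
g00058	0.286869
g00059	15.4005
g00060	1.76948
g00061	0.0353876
g00062	5.34569
g00063	2.42679
g00064	0.358295
g00065	6.28515
g00066	1.53896
g00067	17.7864
g00068	0.0808301
g00069	10.0065
g00070	0.450039
g00071	0.314551
g00072	2.77108
g00073	1.06173
g00074	2.14843
g00075	23.4632
g00076	3.63166
g00077	0.000317876
g00078	1.18734
g00079	0.60744
g00080	16.5713
g00081	8.72537
g00082	2.00802
g00083	1.71391
g00084	0.98813
g00085	0.0625981
g00086	0.21858
g00087	0.259798
g00088	3.21659
g00089	0.0689347
g00090	14.5055
g00091	0.00388529
g00092	5.89913
g00093	5.1226
g00094	0.156277
g00095	0.487087
g00096	0.303799
g00097	0.0193117
g00098	0.714338
g00099	0.430731
g00100	0.516256
g00101	0.0834887
g00102	0.784072
g00103	1.98616
g00104	0.129399
g00105	3.68575
g00106	22.5152
g00107	18.6811
g00108	0.1574
g00109	14.4767
g00110	3.32857
g00111	0.273357
g00112	2.40381
g00113	0.773839
g00114	0.926423
g00115	18.5833
g00116	0.303509
g00117	2.71622
g00118	6.55846
g00119	0.0434526
g00120	1.23034
g00121	2.32309
g00122	0.0672514
g00123	4.98638
g00124	0.341382
g00125	0.0136273
g00126	0.00443982
g00127	0.801604
g00128	6.43719
g00129	0.0997996
g00130	0.00465274
g00131	12.4067
g00132	1.72857
g00133	0.697094
g00134	0.114367
g00135	0.0534494
g00136	0.256588
g00137	1.2652
g00138	3.14753
g00139	0.607364
g00140	0.0281733
g00141	0.00473156
g00142	0.213474
g00143	5.41069
g00144	0.00171818
g00145	0.139155
g00146	0.173486
g00147	0.572704
g00148	0.377909
g00149	0.368994
g00150	0.847857
g00151	37.1759
g00152	0.372026
g00153	0.00101869
g00154	4.82131
g00155	31.8458
g00156	0.493015
g00157	0.307431
g00158	20.2381
g00159	0.82334
g00160	3.54099
g00161	0.328624
g00162	0.429521
g00163	0.00406159
g00164	0.0151277
g00165	0.0531056
g00166	2.44487
g00167	31.3572
g00168	41.0341
g00169	0.00948986
g00170	0.0493987
g00171	0.626271
g00172	0.0045491
g00173	5.62885
g00174	1.38627
g00175	0.5643
g00176	3.60537
g00177	2.90117
g00178	1.02799
g00179	0.000189239
g00180	0.133661
g00181	0.285916
g00182	9.80179
g00183	2.10899
g00184	0.27448
g00185	0.269599
g00186	1.32683
g00187	0.828793
g00188	5.92825e-06
g00189	0.0481691
g00190	10.6924
g00191	1.72251
g00192	0.385706
g00193	2.38542
g00194	1.71414
g00195	0.284691
g00196	0.0907183
g00197	0.658265
g00198	0.556861
g00199	2.26203
g00200	0.0775473
g00201	0.260069
g00202	0.837222
g00203	0.572319
g00204	0.000177795
g00205	1.7489
g00206	0.549147
g00207	1.49001
g00208	0.0649352
g00209	0.411935
g00210	0.0486031
g00211	0.861253
g00212	0.154235
g00213	0.116588
g00214	0.749985
g00215	0.000283368
g00216	3.5282
g00217	0.011678
g00218	0.0880083
g00219	0.61014
g00220	0.178329
g00221	0.295276
g00222	0.80026
g00223	0.0621441
g00224	1.56976
g00225	0.0765185
g00226	15.6939
g00227	6.38374
g00228	11.4125
g00229	18.0885
g00230	5.28655
g00231	2.95872
g00232	1.14787
g00233	0.77571
g00234	0.126343
g00235	0.00051471
g00236	1.56609
g00237	0.525847
g00238	0.0302307
g00239	2.74632
g00240	0.212881
g00241	0.195134
g00242	0.455585
g00243	16.3898
g00244	1.84981
g00245	0.0136539
g00246	0.215113
g00247	0.475794
g00248	2.90438
g00249	3.30403
g00250	3.15567
g00251	5.57925
g00252	0.309173
g00253	0.225994
g00254	0.00672744
g00255	0.752205
g00256	1.36207
g00257	5.44587
g00258	49.0128
g00259	1.82108
g00260	0.387227
g00261	0.567048
g00262	5.21799
g00263	0.0219795
g00264	6.09722
g00265	0.566629
g00266	0.523398
g00267	2.61114
g00268	0.671212
g00269	2.91719
g00270	0.225378
g00271	2.06409
g00272	0.378679
g00273	14.7586
g00274	2.3512
g00275	6.00078
g00276	0.531776
g00277	6.63658
g00278	1.37067
g00279	15.1082
g00280	29.4914
g00281	0.579143
g00282	7.75942e-05
g00283	8.16048
g00284	0.653206
g00285	11.4661
g00286	0.14629
g00287	6.78686
g00288	0.25806
g00289	9.90525
g00290	5.60249
g00291	0.0379638
g00292	3.89793
g00293	0.0848407
g00294	23.2952
g00295	7.78914
g00296	0.309398
g00297	14.1985
g00298	2.03912
g00299	12.6536
g00300	8.18742
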