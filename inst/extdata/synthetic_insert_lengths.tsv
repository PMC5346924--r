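length	count
100	5499
101	5542
102	5585
103	5628
104	5670
105	5711
106	5752
107	5792
108	5831
109	5870
110	5908
111	5946
112	5983
113	6019
114	6054
115	6089
116	6123
117	6156
118	6188
119	6220
120	6250
121	6280
122	6309
123	6337
124	6365
125	6391
126	6417
127	6441
128	6465
129	6488
130	6510
131	6530
132	6550
133	6569
134	6587
135	6604
136	6620
137	6635
138	6649
139	6662
140	6674
141	6685
142	6695
143	6704
144	6712
145	6719
146	6725
147	6729
148	6733
149	6736
150	6737
151	6738
152	6737
153	6736
154	6733
155	6729
156	6725
157	6719
158	6712
159	6704
160	6695
161	6685
162	6674
163	6662
164	6649
165	6635
166	6620
167	6604
168	6587
169	6569
170	6550
171	6530
172	6510
173	6488
174	6465
175	6441
176	6417
177	6391
178	6365
179	6337
180	6309
181	6280
182	6250
183	6220
184	6188
185	6156
186	6123
187	6089
188	6054
189	6019
190	5983
191	5946
192	5908
193	5870
194	5831
195	5792
196	5752
197	5711
198	5670
199	5628
200	5585
201	5542
202	5499
203	5455
204	5410
205	5365
206	5320
207	5274
208	5227
209	5181
210	5133
211	5086
212	5038
213	4990
214	4941
215	4893
216	4844
217	4794
218	4745
219	4695
220	4645
221	4595
222	4544
223	4494
224	4443
225	4393
226	4342
227	4291
228	4240
229	4189
230	4138
231	4087
232	4036
233	3984
234	3933
235	3882
236	3832
237	3781
238	3730
239	3679
240	3629
241	3578
242	3528
243	3478
244	3428
245	3378
246	3329
247	3280
248	3231
249	3182
250	3133
251	3085
252	3037
253	2989
254	2941
255	2894
256	2847
257	2801
258	2755
259	2709
260	2663
261	2618
262	2573
263	2529
264	2485
265	2441
266	2398
267	2355
268	2312
269	2270
270	2229
271	2187
272	2147
273	2106
274	2066
275	2027
276	1988
277	1949
278	1911
279	1873
280	1836
281	1799
282	1763
283	1727
284	1692
285	1657
286	1622
287	1588
288	1555
289	1522
290	1489
291	1457
292	1425
293	1394
294	1364
295	1333
296	1304
297	1274
298	1245
299	1217
300	1189
301	1162
302	1135
303	1108
304	1082
305	1056
306	1031
307	1006
308	982
309	958
310	935
311	912
312	889
313	867
314	845
315	824
316	803
317	783
318	763
319	743
320	724
321	705
322	686
323	668
324	650
325	633
326	616
327	599
328	583
329	567
330	551
331	536
332	521
333	507
334	492
335	478
336	465
337	452
338	439
339	426
340	414
341	401
342	390
343	378
344	367
345	356
346	345
347	335
348	325
349	315
350	305
351	296
352	287
353	278
354	269
355	261
356	253
357	245
358	237
359	229
360	222
361	215
362	208
363	201
364	195
365	188
366	182
367	176
368	170
369	164
370	159
371	154
372	148
373	143
374	138
375	134
376	129
377	125
378	120
379	116
380	112
381	108
382	104
383	101
384	97
385	93
386	90
387	87
388	84
389	81
390	78
391	75
392	72
393	69
394	67
395	64
396	62
397	60
398	57
399	55
400	53
401	51
402	49
403	47
404	45
405	44
406	42
407	40
408	39
409	37
410	36
411	34
412	33
413	32
414	30
415	29
416	28
417	27
418	26
419	25
420	24
421	23
422	22
423	21
424	20
425	19
426	18
427	18
428	17
429	16
430	15
431	15
432	14
433	13
434	13
435	12
436	12
437	11
438	11
439	10
440	10
441	9
442	9
443	9
444	8
445	8
446	8
447	7
448	7
449	7
450	6
451	6
452	6
453	5
454	5
455	5
456	5
457	4
458	4
459	4
460	4
461	4
462	4
463	3
464	3
465	3
466	3
467	3
468	3
469	2
470	2
471	2
472	2
473	2
474	2
475	2
476	2
477	2
478	2
479	2
480	1
481	1
482	1
483	1
484	1
485	1
486	1
487	1
488	1
489	1
490	1
491	1
492	1
493	1
494	1
495	1
496	1
497	1
498	1
499	1
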