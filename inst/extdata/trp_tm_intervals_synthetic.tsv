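gene	start	end
TRPA1	504	524
TRPA1	589	609
TRPA1	674	694
TRPA1	760	780
TRPA1	845	865
TRPA1	930	950
TRPC1	357	377
TRPC1	416	436
TRPC1	475	495
TRPC1	535	555
TRPC1	594	614
TRPC1	653	673
TRPC2	527	547
TRPC2	617	637
TRPC2	706	726
TRPC2	796	816
TRPC2	885	905
TRPC2	975	995
TRPC3	382	402
TRPC3	446	466
TRPC3	509	529
TRPC3	573	593
TRPC3	636	656
TRPC3	700	720
TRPC4	440	460
TRPC4	514	534
TRPC4	588	608
TRPC4	661	681
TRPC4	735	755
TRPC4	809	829
TRPC5	438	458
TRPC5	512	532
TRPC5	585	605
TRPC5	659	679
TRPC5	732	752
TRPC5	806	826
TRPC6	419	439
TRPC6	489	509
TRPC6	559	579
TRPC6	630	650
TRPC6	700	720
TRPC6	770	790
TRPC7	388	408
TRPC7	453	473
TRPC7	518	538
TRPC7	582	602
TRPC7	647	667
TRPC7	712	732
TRPM1	721	741
TRPM1	845	865
TRPM1	969	989
TRPM1	1094	1114
TRPM1	1218	1238
TRPM1	1342	1362
TRPM2	676	696
TRPM2	792	812
TRPM2	908	928
TRPM2	1025	1045
TRPM2	1141	1161
TRPM2	1257	1277
TRPM3	768	788
TRPM3	900	920
TRPM3	1033	1053
TRPM3	1165	1185
TRPM3	1298	1318
TRPM3	1430	1450
TRPM4	546	566
TRPM4	639	659
TRPM4	732	752
TRPM4	825	845
TRPM4	918	938
TRPM4	1011	1031
TRPM5	524	544
TRPM5	613	633
TRPM5	702	722
TRPM5	791	811
TRPM5	880	900
TRPM5	969	989
TRPM6	910	930
TRPM6	1068	1088
TRPM6	1225	1245
TRPM6	1383	1403
TRPM6	1540	1560
TRPM6	1698	1718
TRPM7	839	859
TRPM7	984	1004
TRPM7	1129	1149
TRPM7	1274	1294
TRPM7	1419	1439
TRPM7	1564	1584
TRPM8	497	517
TRPM8	581	601
TRPM8	665	685
TRPM8	749	769
TRPM8	833	853
TRPM8	917	937
TRPV1	378	398
TRPV1	441	461
TRPV1	504	524
TRPV1	566	586
TRPV1	629	649
TRPV1	692	712
TRPV2	344	364
TRPV2	401	421
TRPV2	458	478
TRPV2	514	534
TRPV2	571	591
TRPV2	628	648
TRPV3	356	376
TRPV3	415	435
TRPV3	474	494
TRPV3	533	553
TRPV3	592	612
TRPV3	651	671
TRPV4	392	412
TRPV4	457	477
TRPV4	523	543
TRPV4	588	608
TRPV4	654	674
TRPV4	719	739
TRPV5	328	348
TRPV5	382	402
TRPV5	436	456
TRPV5	491	511
TRPV5	545	565
TRPV5	599	619
TRPV6	326	346
TRPV6	380	400
TRPV6	434	454
TRPV6	487	507
TRPV6	541	561
TRPV6	595	615
MCOLN1	261	281
MCOLN1	303	323
MCOLN1	345	365
MCOLN1	388	408
MCOLN1	430	450
MCOLN1	472	492
MCOLN2	255	275
MCOLN2	296	316
MCOLN2	337	357
MCOLN2	378	398
MCOLN2	419	439
MCOLN2	460	480
MCOLN3	249	269
MCOLN3	289	309
MCOLN3	329	349
MCOLN3	369	389
MCOLN3	409	429
MCOLN3	449	469
PKD2	436	456
PKD2	509	529
PKD2	582	602
PKD2	656	676
PKD2	729	749
PKD2	802	822
PKD2L1	362	382
PKD2L1	422	442
PKD2L1	482	502
PKD2L1	543	563
PKD2L1	603	623
PKD2L1	663	683
PKD2L2	281	301
PKD2L2	327	347
PKD2L2	372	392
PKD2L2	418	438
PKD2L2	463	483
PKD2L2	509	529
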