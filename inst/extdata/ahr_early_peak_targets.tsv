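# Published differential-transcription values for 21 early-peak targets of
# wood smoke particle exposure in airway epithelial cells (AHR pathway;
# nascent-transcription study deposited as GEO GSE167372). Used as the
# worked example for temporal cluster classification. padj values printed
# as 0 denote adjusted p-values that round to zero.
gene	lfc_30v0	padj_30v0	lfc_120v30	padj_120v30
IL24	5.757	0	-2.359	6.81E-141
EGR1	5.491	0	-4.790	0
KRT17	5.128	0	-2.467	0
LHX4	5.066	0	-2.421	3.72E-152
MAFF	4.412	0	-2.869	0
TAGLN	4.169	0	-2.988	0
CCN2	3.798	0	-3.018	0
SPOCD1	3.629	0	-1.928	1.75E-158
TIPARP	2.777	0	-1.975	1.37E-282
SRF	2.773	0	-2.202	5.42E-218
MYH9	2.756	0	-1.797	6.60E-282
CYP1B1	2.508	0	-1.384	9.16E-126
DNMT3L	3.802	8.63E-280	-2.116	1.34E-116
AHRR	1.794	2.22E-238	-0.737	4.55E-41
CYP1A1	5.410	1.51E-224	-1.466	4.35E-45
ALDH3A1	2.512	2.58E-124	-0.992	1.21E-22
ARNT2	1.262	5.65E-72	-0.590	7.75E-17
MT2A	1.318	1.63E-64	-1.328	1.34E-64
MEF2A	0.836	4.16E-35	-0.994	6.95E-49
CCR7	2.153	1.43E-32	-1.560	1.24E-18
CYP1A2	4.662	7.97E-11	-2.324	9.82E-06
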