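pathway	reported_aggregate_p	p_rnaseq	p_array1	p_array2
Regulation of nuclear SMAD2/3 signaling	4.13E-06	0.012	0.001	0.002
CD4 T cell receptor signaling	4.74E-06	0.014	0.001	0.002
TCR signaling in naive CD4+ T cells	5.93E-06	0.018	0.001	0.002
IL2 signaling events mediated by STAT5	1.07E-05	0.001	0.010	0.007
Angiopoietin receptor Tie2-mediated signaling	1.82E-05	0.001	0.002	0.064
TRAIL signaling pathway	1.87E-05	0.033	0.002	0.002
Signaling events mediated by HDAC Class II	2.46E-05	0.030	0.001	0.006
Neurotrophic factor-mediated Trk receptor signaling	3.22E-05	0.061	0.001	0.004
Canonical Wnt signaling pathway Diagram	3.41E-05	0.009	0.001	0.029
Cellular roles of Anthrax toxin	5.90E-05	0.008	0.001	0.061
Methionine and Cysteine metabolism	6.62E-05	0.556	0.001	0.001
mRNA splicing	6.65E-05	0.040	0.007	0.002
Integrin signaling pathway	6.94E-05	0.006	0.001	0.098
Validated nuclear estrogen receptor alpha network	7.38E-05	0.158	0.004	0.001
Wnt signaling pathway	7.87E-05	0.010	0.001	0.068
Arf6 signaling events	1.0E-04	0.116	0.002	0.004
Alpha4 beta1 integrin signaling events	1.2E-04	0.095	0.006	0.002
FGF signaling pathway	1.2E-04	0.009	0.004	0.032
Syndecan-4-mediated signaling events	1.2E-04	0.003	0.055	0.007
AP-1 transcription factor network	1.7E-04	0.003	0.009	0.063
Signaling events mediated by focal adhesion kinase	2.1E-04	0.009	0.001	0.233
a6b1 and a6b4 Integrin signaling	3.0E-04	0.002	0.005	0.319
ATM pathway	5.9E-04	0.003	0.005	0.472
Validated targets of C-MYC transcriptional repression	6.2E-04	0.009	0.001	0.833
Apoptosis signaling pathway	6.3E-04	0.005	0.002	0.767
Angiogenesis	6.5E-04	0.010	0.005	0.161
Cadherin signaling pathway	7.2E-04	0.009	0.006	0.167
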