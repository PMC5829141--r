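region	condition	latN	latP	ampN	ampP	width	gateN	gateP	isi	noiseAmp	nTrials	fs	assrAmp	assrPhaseJitterSd	assrNoiseAmp	fStim	trainDur
AC	conscious	0.025	0.040	-60	45	0.012	0.75	0.90	0.5	30	120	1000	28	0.4	30	40	0.5
AC	anesthetized	0.025	0.040	-51	38	0.012	0.72	0.92	0.5	30	120	1000	11.2	0.8	30	40	0.5
HP	conscious	0.039	0.065	-60	45	0.012	0.61	0.51	0.5	30	120	1000	10	0.4	30	40	0.5
HP	anesthetized	0.039	0.065	-51	38	0.012	0.58	0.45	0.5	30	120	1000	4	0.8	30	40	0.5
AMY	conscious	0.037	0.065	-60	45	0.012	0.50	0.35	0.5	30	120	1000	5	0.4	30	40	0.5
AMY	anesthetized	0.037	0.065	-51	38	0.012	0.52	0.30	0.5	30	120	1000	2	0.8	30	40	0.5
PFC	conscious	0.035	0.075	-60	45	0.012	0.25	0.28	0.5	30	120	1000	0	0.4	30	40	0.5
PFC	anesthetized	0.035	0.075	-51	38	0.012	0.21	0.23	0.5	30	120	1000	0	0.8	30	40	0.5
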