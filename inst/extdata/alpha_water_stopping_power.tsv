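# Total stopping power of alpha particles in liquid water (density 1.0 g/cm^3).
# Compiled by hand from standard ICRU-49 / ASTAR-style stopping-power
# tabulations; values in keV/um (numerically MeV cm^2/g divided by 10 at
# unit density). Electronic stopping dominates over the tabulated domain;
# nuclear stopping is negligible above ~0.1 MeV and is not separated out.
# Columns: energy_MeV let_keV_um
energy_MeV	let_keV_um
0.025	72.0
0.05	95.0
0.10	127.0
0.15	147.4
0.20	161.1
0.30	176.8
0.40	185.2
0.50	189.4
0.60	190.7
0.70	190.0
0.80	188.0
0.90	185.0
1.00	181.6
1.25	172.0
1.50	162.5
1.75	153.5
2.00	145.5
2.25	138.2
2.50	131.6
2.75	125.6
3.00	120.2
3.50	111.0
4.00	103.2
4.50	96.5
5.00	90.7
5.50	85.6
6.00	81.1
6.50	77.1
7.00	73.4
7.50	70.1
8.00	67.1
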