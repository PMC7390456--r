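name	value	unit	group	note
kon1C	4	uM-1.s-1	ca_cam	1st Ca on C-lobe of free CaM
koff1C	40.24	s-1	ca_cam
kon2C	10	uM-1.s-1	ca_cam	2nd Ca on C-lobe of free CaM
koff2C	9.3	s-1	ca_cam
kon1N	100	uM-1.s-1	ca_cam	1st Ca on N-lobe of free CaM
koff1N	2660	s-1	ca_cam
kon2N	150	uM-1.s-1	ca_cam	2nd Ca on N-lobe of free CaM
koff2N	990	s-1	ca_cam
konCaM0	0.0038	uM-1.s-1	cam_camkii	source prints M-1.s-1; read as uM-1.s-1 for consistency with sibling rows
koffCaM0	6.56	s-1	cam_camkii
konCaM1C	0.059	uM-1.s-1	cam_camkii
koffCaM1C	6.72	s-1	cam_camkii
konCaM2C	0.92	uM-1.s-1	cam_camkii
koffCaM2C	6.35	s-1	cam_camkii
konCaM1C1N	0.33	uM-1.s-1	cam_camkii
koffCaM1C1N	5.68	s-1	cam_camkii
konCaM2C1N	5.2	uM-1.s-1	cam_camkii
koffCaM2C1N	5.25	s-1	cam_camkii
konCaM1N	0.022	uM-1.s-1	cam_camkii
koffCaM1N	5.75	s-1	cam_camkii
konCaM2N	0.1	uM-1.s-1	cam_camkii
koffCaM2N	1.68	s-1	cam_camkii
konCaM1C2N	1.9	uM-1.s-1	cam_camkii
koffCaM1C2N	2.09	s-1	cam_camkii
konCaM4	30	uM-1.s-1	cam_camkii
koffCaM4	1.95	s-1	cam_camkii
konK1C	44	uM-1.s-1	ca_camk	1st Ca on C-lobe of CaMKII-bound CaM
koffK1C	29.04	s-1	ca_camk
konK2C	44	uM-1.s-1	ca_camk
koffK2C	2.42	s-1	ca_camk
konK1N	75	uM-1.s-1	ca_camk
koffK1N	301.5	s-1	ca_camk
konK2N	76	uM-1.s-1	ca_camk
koffK2N	32.68	s-1	ca_camk
konCaMKII	50	uM-1.s-1	dimer	monomer model only: CaM-bound monomers pair up
koffCaMKII	60	s-1	dimer
kpCaM1C	0.032	s-1	phospho	substrate CaM has 1 Ca on C-lobe
kpCaM2C	0.064	s-1	phospho
kpCaM1C1N	0.094	s-1	phospho
kpCaM2C1N	0.124	s-1	phospho
kpCaM1N	0.061	s-1	phospho
kpCaM2N	0.12	s-1	phospho
kpCaM1C2N	0.154	s-1	phospho
kpCaM4	0.96	s-1	phospho
kponCaM0	0.00127	uM-1.s-1	cam_pcamkii	CaM binding to phosphorylated CaMKII
kponCaM1C	19.7	uM-1.s-1	cam_pcamkii
kponCaM2C	0.3	uM-1.s-1	cam_pcamkii
kponCaM1C1N	1.1	uM-1.s-1	cam_pcamkii
kponCaM2C1N	1.73	uM-1.s-1	cam_pcamkii
kponCaM1N	7.3	uM-1.s-1	cam_pcamkii
kponCaM2N	0.03	uM-1.s-1	cam_pcamkii
kponCaM1C2N	0.63	uM-1.s-1	cam_pcamkii
kponCaM4	10	uM-1.s-1	cam_pcamkii
kpoffCaM	0.07	s-1	cam_pcamkii	CaM unbinding from phosphorylated CaMKII (trapping)
konNg	5	uM-1.s-1	ng	Ng binds Ca-free CaM only
koffNg	1	s-1	ng
kcat	0.41	s-1	pp1	PP1 catalytic rate
Km	11	uM	pp1	PP1 Michaelis constant
konPP1	10	uM-1.s-1	pp1	explicit enzyme-substrate on-rate; koffPP1 derived so (koff+kcat)/kon = Km
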