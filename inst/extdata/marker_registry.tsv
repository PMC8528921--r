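family_id	process	identity_threshold	reference_length_bp	is_single_copy_ribosomal
NiFe_group1h	H2 oxidation (1h)	50	1800	FALSE
NiFe_group1l	H2 oxidation (1l)	50	1770	FALSE
NiFe_group1d	H2 oxidation (1d)	50	1770	FALSE
NiFe_group1f	H2 oxidation (1f)	50	1710	FALSE
NiFe_group2a	H2 oxidation (2a)	50	1680	FALSE
NiFe_group3b	H2 cycling (3b)	50	1740	FALSE
NiFe_group3d	H2 cycling (3d)	50	1620	FALSE
NiFe_group4	H2 evolution (group 4)	60	1680	FALSE
FeFe	H2 cycling (FeFe)	60	1350	FALSE
RbcL_IA	carbon fixation (RuBisCO IA)	50	1410	FALSE
RbcL_IB	carbon fixation (RuBisCO IB)	50	1410	FALSE
RbcL_IE	carbon fixation (RuBisCO IE)	50	1410	FALSE
RbcL_IV	RuBisCO-like (IV)	50	1410	FALSE
AclB	carbon fixation (rTCA)	50	1800	FALSE
AcsB	carbon fixation (Wood-Ljungdahl)	50	2190	FALSE
McrA	methanogenesis	50	1650	FALSE
MmoX	methane oxidation (soluble)	50	1590	FALSE
PmoA	methane oxidation (particulate)	50	750	FALSE
MxaF	methanol oxidation	50	1800	FALSE
FdhA	formate oxidation	50	2850	FALSE
NuoF	NADH dehydrogenase	50	1290	FALSE
SdhA	succinate dehydrogenase	50	1770	FALSE
AtpA	ATP synthase	50	1530	FALSE
CtaD	terminal oxidase (aa3)	50	1650	FALSE
CcoN	terminal oxidase (cbb3)	50	1440	FALSE
CyoA	terminal oxidase (bo3)	50	945	FALSE
CydA	terminal oxidase (bd)	50	1560	FALSE
NifH	nitrogen fixation	50	870	FALSE
NarG	nitrate reduction (Nar)	50	3690	FALSE
NapA	nitrate reduction (Nap)	50	2490	FALSE
NirS	nitrite reduction (cd1)	50	1680	FALSE
NirK	nitrite reduction (Cu)	50	1020	FALSE
NorB	nitric oxide reduction	50	1380	FALSE
NosZ	nitrous oxide reduction	50	1920	FALSE
NrfA	ammonification	50	1440	FALSE
DsrA	sulfite reduction	50	1260	FALSE
Sqr	sulfide oxidation	50	1290	FALSE
FccB	sulfide oxidation (flavocytochrome)	50	1290	FALSE
SoxB	thiosulfate oxidation	50	1680	FALSE
AioA	arsenite oxidation	50	2550	FALSE
ArrA	arsenate respiration	50	2580	FALSE
Cyc2	iron oxidation	50	1350	FALSE
CooS	anaerobic CO oxidation	50	1890	FALSE
NxrA	nitrite oxidation	60	3450	FALSE
AmoA	ammonia oxidation	60	750	FALSE
CoxL	CO oxidation (form I)	60	2370	FALSE
PsbA	photosystem II	70	1080	FALSE
IsoA	isoprene oxidation	70	1650	FALSE
HbsT	sulfur trafficking (HbsT)	75	480	FALSE
PsaA	photosystem I	80	2250	FALSE
RHO	energy-converting rhodopsin	40	750	FALSE
rplB	ribosomal protein L2	50	819	TRUE
rplC	ribosomal protein L3	50	627	TRUE
rplD	ribosomal protein L4	50	603	TRUE
rplE	ribosomal protein L5	50	537	TRUE
rplF	ribosomal protein L6	50	531	TRUE
rplK	ribosomal protein L11	50	423	TRUE
rplN	ribosomal protein L14	50	366	TRUE
rplP	ribosomal protein L16	50	408	TRUE
rpsB	ribosomal protein S2	50	720	TRUE
rpsC	ribosomal protein S3	50	699	TRUE
rpsE	ribosomal protein S5	50	498	TRUE
rpsG	ribosomal protein S7	50	468	TRUE
rpsJ	ribosomal protein S10	50	309	TRUE
rpsS	ribosomal protein S19	50	276	TRUE
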