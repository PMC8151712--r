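specimen_id	country	location	collection_date	stage	accession_tpi	accession_coi
Con-11	DR Congo	Katana, Kabare	11/29/2018	Larva	MT894220	MT103350
Con-12	DR Congo	Miti, Kabare	11/29/2018	Larva	MT894221	MT933052
Con-21	DR Congo	Minova, Kalehe	11/29/2018	Larva	MT894222	MT933053
Con-31	DR Congo	Luvungi, Uvira	12/15/2018	Larva	MT894223	MT933054
Con-41	DR Congo	Sange, Uvira	12/15/2018	Larva	MT894224	MT933055
Con-42	DR Congo	Nduba, Walungu	12/15/2018	Larva	MT894225	MT103349
Tan-1	Tanzania	Arusha, Tengeru	1/10/2019	Larva	MT894226	MT103348
Tan-2	Tanzania	Mlali, Morogoro	1/17/2019	Larva	MT894227	MT933056
Tan-3	Tanzania	Sri, Pwani	1/10/2019	Larva	MT894228	MT933057
Tan-4	Tanzania	Sua, Morogoro	1/14/2019	Larva	MT894229	MT933058
Uga-1	Uganda	Mbale	1/10/2018	Larva	MT894230	MT933059
Uga-2	Uganda	Masindi	10/17/2017	Larva	MT894231	MT933060
Uga-3	Uganda	Kole	10/18/2018	Larva	MT894232	MT933061
Uga-4	Uganda	Luwero	10/15/2018	Larva	MT894233	MT933062
Zim-1	Zimbabwe	Harare research station, Harare	2/8/2019	Larva	MT894234	MT103346
Zim-2	Zimbabwe	Chipinge, Manicaland	2/22/2019	Larva	MT894235	MT103347
Ban-1	Bangladesh	Dhaka	8/14/2019	Larva	MT894236	MT933063
Kor-1	Korea	Jeju	9/19/2019	Adult	MT894237	MT933064
Kor-2	Korea	Gyeongsan	8/29/2019	Larva	MT894238	MT103342
Kor-3	Korea	Gyeongsan	6/10/2020	Larva	MT894239	MT933065
Kor-4	Korea	Jeju	6/9/2020	Adult	MT894240	MT933066
Nep-1	Nepal	Bhakundebesi, Kavre	9/24/2019	Larva	MT894241	MT103345
Nep-2	Nepal	Khumaltar, Lalitpur	7/30/2019	Larva	MT894242	MT933067
Nep-3	Nepal	Khaira, Pyathan	8/6/2019	Larva	MT894243	MT933068
Vie-1	Vietnam	Ninh Binh	9/30/2019	Adult	MT894244	MT103334
Vie-2	Vietnam	Vinh Phuc	9/30/2019	Adult	MT894245	MT103335
Vie-3	Vietnam	Hanoi	9/30/2019	Larva	MT894246	MT103336
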