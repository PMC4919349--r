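strain_name	collection_id	growth_conditions	source
Corallococcus coralloides	DSM 2259	DSMZ medium 222, 30C, shaking 200 rpm; stationary-phase liquid culture	DSMZ
Cystobacter fuscus	DSM 2262	DSMZ medium 222, 30C, shaking 200 rpm; stationary-phase liquid culture	DSMZ
Enhygromyxa salina	DSM 15201	DSMZ medium 958 agar plates, 30C; cells scraped off plates	DSMZ
Fluviicola taffensis	DSM 16823	DSMZ medium 1 liquid, 30C, shaking 200 rpm; stationary-phase liquid culture	DSMZ
Methylobacter luteus	IMV-B-3098	NMS medium plus methane, 30C, shaking 200 rpm; stationary-phase liquid culture	M.G. Kalyuzhnaya, San Diego State University
Methylobacter whittenburyi	ACM 3310	NMS medium plus methane, 30C, shaking 200 rpm; stationary-phase liquid culture	M.G. Kalyuzhnaya, San Diego State University
Methyloceanibacter caenitepidi	DSM 27242	DSMZ medium 1488 plus 1% methanol, 37C, shaking 200 rpm; stationary-phase liquid culture	M.G. Kalyuzhnaya, San Diego State University
Methylococcus capsulatus Texas	ATCC 19069	NMS medium plus methane, 30C, shaking 200 rpm; stationary-phase liquid culture	ATCC
Methylosarcina lacus	LW14	NMS medium plus methane, 30C, shaking 200 rpm; stationary-phase liquid culture	M.G. Kalyuzhnaya, San Diego State University
Plesiocystis pacifica	DSM 14875	DSMZ medium 958 agar plates, 30C; cells scraped off plates	DSMZ
Sandaracinus amylolyticus	DSM 53668	DSMZ medium 67 agar plates, 30C; cells scraped off plates	DSMZ
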