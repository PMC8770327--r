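food	substance	value	unit	basis	censoring	censor_limit
Grains>Pasta	iodine	10	ug/kg	wet	measured	NA
Algae>Seaweed pasta	iodine	29200	ug/kg	wet	measured	NA
Meat>Bacon	iodine	136	ug/kg	wet	measured	NA
Algae>Seaweed bacon	iodine	163000	ug/kg	wet	measured	NA
Vegetables>Lettuce>Rocket lettuce	iodine	0	ug/kg	wet	measured	NA
Algae>Seaweed lettuce	iodine	75530	ug/kg	wet	measured	NA
Grains>Pasta	sodium	55	mg/kg	wet	measured	NA
Algae>Seaweed pasta	sodium	7240	mg/kg	wet	measured	NA
Meat>Bacon	sodium	12452	mg/kg	wet	measured	NA
Algae>Seaweed bacon	sodium	12400	mg/kg	wet	measured	NA
Vegetables>Lettuce>Rocket lettuce	sodium	250	mg/kg	wet	measured	NA
Algae>Seaweed lettuce	sodium	2330	mg/kg	wet	measured	NA
Grains>Pasta	t_arsenic	21	ug/kg	wet	measured	NA
Algae>Seaweed pasta	t_arsenic	40333	ug/kg	dry	measured	NA
Meat>Bacon	t_arsenic	15	ug/kg	wet	measured	NA
Algae>Seaweed bacon	t_arsenic	40333	ug/kg	wet	measured	NA
Vegetables>Lettuce>Rocket lettuce	t_arsenic	20	ug/kg	wet	measured	NA
Algae>Seaweed lettuce	t_arsenic	40333	ug/kg	dry	measured	NA
Grains>Pasta	i_arsenic	15	ug/kg	wet	measured	NA
Algae>Seaweed pasta	i_arsenic	50	ug/kg	dry	measured	NA
Meat>Bacon	i_arsenic	11	ug/kg	wet	measured	NA
Algae>Seaweed bacon	i_arsenic	50	ug/kg	wet	measured	NA
Vegetables>Lettuce>Rocket lettuce	i_arsenic	13	ug/kg	wet	measured	NA
Algae>Seaweed lettuce	i_arsenic	50	ug/kg	dry	measured	NA
Grains>Pasta	cadmium	14	ug/kg	wet	measured	NA
Algae>Seaweed pasta	cadmium	443	ug/kg	dry	measured	NA
Meat>Bacon	cadmium	7	ug/kg	wet	measured	NA
Algae>Seaweed bacon	cadmium	443	ug/kg	wet	measured	NA
Vegetables>Lettuce>Rocket lettuce	cadmium	36	ug/kg	wet	measured	NA
Algae>Seaweed lettuce	cadmium	443	ug/kg	dry	measured	NA
Grains>Pasta	lead	8	ug/kg	wet	measured	NA
Algae>Seaweed pasta	lead	111	ug/kg	dry	measured	NA
Meat>Bacon	lead	11	ug/kg	wet	measured	NA
Algae>Seaweed bacon	lead	111	ug/kg	wet	measured	NA
Vegetables>Lettuce>Rocket lettuce	lead	30	ug/kg	wet	measured	NA
Algae>Seaweed lettuce	lead	111	ug/kg	dry	measured	NA
Grains>Pasta	mercury	10	ug/kg	wet	measured	NA
Algae>Seaweed pasta	mercury	0	ug/kg	wet	LOQ	0.90
Meat>Bacon	mercury	3	ug/kg	wet	measured	NA
Algae>Seaweed bacon	mercury	0	ug/kg	wet	LOQ	0.90
Vegetables>Lettuce>Rocket lettuce	mercury	2	ug/kg	wet	measured	NA
Algae>Seaweed lettuce	mercury	0	ug/kg	wet	LOQ	0.90
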