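group_id	accession	taxid	species	genus	family	order	class	phylum
pBII_1	CP009797.1		Burkholderia ambifaria		Burkholderiaceae			Proteobacteria
pBII_1	CP017455.1		Dickeya solani		Pectobacteriaceae			Proteobacteria
pMACZ	CP001979.1		Marinobacter adhaerens HP15		Alteromonadaceae			Proteobacteria
pMACZ	CP006601.1		Cycloclasticus zancles 78-ME		Piscirickettsiaceae			Proteobacteria
pKPC-47e	CP008901.1		Enterobacter cloacae ECNIH3		Enterobacteriaceae			Proteobacteria
pKPC-47e	CP008908.1		Enterobacter cloacae ECR091		Enterobacteriaceae			Proteobacteria
pKPC-47e	CP009858.1		Enterobacter cloacae		Enterobacteriaceae			Proteobacteria
pKPC-47e	CP009881.1		Pantoea sp. PSNIH1		Erwiniaceae			Proteobacteria
pMS6671c	CP026060.1		Proteus mirabilis		Morganellaceae			Proteobacteria
pMS6671c	LN824136.1		Klebsiella pneumoniae		Enterobacteriaceae			Proteobacteria
pTTAL_1	NZ_AP018250.1		Tolypothrix tenuis PCC 7101		Tolypothrichaceae			Cyanobacteria
pTTAL_1	NZ_AP018310.1		Aulosira laxa NIES-50		Fortieaceae			Cyanobacteria
pTTAL_2	NZ_AP018251.1		Tolypothrix tenuis PCC 7101		Tolypothrichaceae			Cyanobacteria
pTTAL_2	NZ_AP018311.1		Aulosira laxa NIES-50		Fortieaceae			Cyanobacteria
pTTAL_3	NZ_AP018252.1		Tolypothrix tenuis PCC 7101		Tolypothrichaceae			Cyanobacteria
pTTAL_3	NZ_AP018312.1		Aulosira laxa NIES-50		Fortieaceae			Cyanobacteria
pCAV	CP003994.1		Klebsiella pneumoniae subsp. pneumoniae Kp13		Enterobacteriaceae			Proteobacteria
pCAV	CP011569.1		Enterobacter cloacae		Enterobacteriaceae			Proteobacteria
pCAV	CP011604.1		Citrobacter freundii		Enterobacteriaceae			Proteobacteria
pCAV	CP011637.1		Serratia marcescens		Yersiniaceae			Proteobacteria
pCAV	CP011652.1		Citrobacter freundii		Enterobacteriaceae			Proteobacteria
pCAV	CP018666.1		Klebsiella pneumoniae		Enterobacteriaceae			Proteobacteria
pCAV	CP024487.1		Klebsiella pneumoniae		Enterobacteriaceae			Proteobacteria
pCAV	CP024494.1		Klebsiella pneumoniae		Enterobacteriaceae			Proteobacteria
pCAV	NZ_CP024514.1		Klebsiella pneumoniae		Enterobacteriaceae			Proteobacteria
pECMM	CP010877.1		Escherichia coli		Enterobacteriaceae			Proteobacteria
pECMM	CP019004.1		Escherichia coli		Enterobacteriaceae			Proteobacteria
pECMM	CP019021.1		Escherichia coli		Enterobacteriaceae			Proteobacteria
pECMM	CP023506.1		Morganella morganii		Morganellaceae			Proteobacteria
pMPSE	CP021055.1		Methylobacterium zatmanii		Methylobacteriaceae			Proteobacteria
pMPSE	CP022430.1		Pantoea ananatis		Erwiniaceae			Proteobacteria
pMPSE	CP022493.1		Salmonella enterica subsp. enterica serovar Saintpaul		Enterobacteriaceae			Proteobacteria
pMPSE	CP022496.1		Salmonella enterica subsp. enterica serovar Derby		Enterobacteriaceae			Proteobacteria
pMPSE	CP022501.1		Salmonella enterica subsp. enterica serovar Kentucky str. SA20030505		Enterobacteriaceae			Proteobacteria
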