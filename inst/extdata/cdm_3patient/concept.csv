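concept_id,concept_name,domain,drug_class,condition_group,syndrome_tag
7001,valproic acid,drug,N03A_ingredient,NA,NA
7002,oxcarbazepine,drug,N03A_ingredient,NA,NA
7003,lamotrigine,drug,N03A_ingredient,NA,NA
7004,levetiracetam,drug,N03A_ingredient,NA,NA
7005,topiramate,drug,N03A_ingredient,NA,NA
7006,phenobarbital,drug,N03A_ingredient,NA,NA
7007,rufinamide,drug,N03A_ingredient,NA,NA
7008,perampanel,drug,N03A_ingredient,NA,NA
7009,carbamazepine,drug,N03A_ingredient,NA,NA
7010,clobazam,drug,N03A_ingredient,NA,NA
7011,ethosuximide,drug,N03A_ingredient,NA,NA
7012,vigabatrin,drug,N03A_ingredient,NA,NA
7013,zonisamide,drug,N03A_ingredient,NA,NA
7014,lacosamide,drug,N03A_ingredient,NA,NA
374915,"Localization-related epilepsy, not otherwise specified",condition,NA,focal,other
4185733,Benign epilepsy with centrotemporal spikes,condition,NA,focal,BECTS
4102345,Temporal lobe epilepsy,condition,NA,focal,other
4044080,Childhood occipital epilepsy (Panayiotopoulos type),condition,NA,focal,other
4047888,Frontal lobe epilepsy,condition,NA,focal,other
4046207,Occipital lobe epilepsy (Gastaut type),condition,NA,focal,other
4043551,Epilepsy with continuous spike wave during slow-wave sleep,condition,NA,focal,other
4044084,Supplementary motor area epilepsy,condition,NA,focal,other
4046206,Parietal lobe epilepsy,condition,NA,focal,other
4041672,Rasmussen syndrome,condition,NA,focal,other
4055361,"Generalized epilepsy, not otherwise specified",condition,NA,generalized,other
4179936,Childhood absence epilepsy,condition,NA,generalized,CAE
376105,West syndrome,condition,NA,generalized,other
4046213,Lennox-Gastaut syndrome,condition,NA,generalized,LGS
4267274,Juvenile myoclonic epilepsy,condition,NA,generalized,other
4046210,Juvenile absence epilepsy,condition,NA,generalized,other
4047897,Epilepsy with grand mal seizures on awakening,condition,NA,generalized,other
4043413,Myoclonic astatic epilepsy,condition,NA,generalized,other
4044225,Myoclonic absence epilepsy,condition,NA,generalized,other
9999999,"Epilepsy, unclassified (synthetic)",condition,NA,unclassified,other
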