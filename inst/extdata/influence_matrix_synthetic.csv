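source,target,topic,level
Province,Farmers,FoA1_3,high
NLEU,Farmers,FoA1_3,mandatory
Retail,Farmers,FoA1_3,high
Labels,Farmers,FoA1_3,low
Network,Farmers,FoA1_3,low
FarmerOrgs,Farmers,FoA1_3,low
Consumers,Farmers,FoA1_3,low
NLEU,Province,FoA1_3,high
Province,FarmerOrgs,FoA1_3,low
Farmers,Network,FoA1_3,low
NLEU,Farmers,FoA2,mandatory
Retail,Farmers,FoA2,high
Labels,Farmers,FoA2,high
Network,Farmers,FoA2,low
FarmerOrgs,Farmers,FoA2,low
Province,Farmers,FoA2,low
Consumers,Farmers,FoA2,low
NLEU,Province,FoA2,high
NLEU,Retail,FoA2,low
Consumers,Retail,FoA2,low
Farmers,Network,FoA2,low
Consumers,Farmers,FoA4,high
Network,Farmers,FoA4,high
Retail,Farmers,FoA4,low
Province,Farmers,FoA4,low
FarmerOrgs,Farmers,FoA4,low
Labels,Farmers,FoA4,low
Farmers,Consumers,FoA4,high
Farmers,Network,FoA4,high
Farmers,Retail,FoA4,low
Farmers,Labels,FoA4,low
Province,FarmerOrgs,FoA4,low
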