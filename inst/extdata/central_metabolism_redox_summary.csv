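group,direction,n_reactions,note,examples
G1,reduction,9,activated carboxylic acid to carbonyl or reverse oxidation,glyceraldehyde-3-phosphate dehydrogenase; aspartate-semialdehyde dehydrogenase
G1,oxidation_only,5,irreversible oxidation of carbonyl to un-activated carboxylic acid,pyruvate dehydrogenase (overall); 2-ketoglutarate dehydrogenase (overall)
G2,reduction,20,carbonyl to hydroxycarbon or reverse oxidation,malate dehydrogenase; lactate dehydrogenase; glycerol-3-phosphate dehydrogenase
G3,reduction,18,carbonyl to amine or reverse oxidation,glutamate dehydrogenase; transaminase-coupled aminations
G4,reduction,4,irreversible reduction of hydroxycarbon to hydrocarbon,enoyl-ACP reductase steps of fatty-acid synthesis
G4,oxidation_only,2,hydrocarbon oxidations above the NAD(P) range requiring alternative carriers,succinate to fumarate; dihydroorotate to orotate
G4,oxidation_aromatic,2,formally G4 oxidations made favorable by aromatic ring formation,prephenate to 4-hydroxyphenylpyruvate; arogenate to tyrosine
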