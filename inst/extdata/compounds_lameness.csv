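# Local compound table for the dried-milk-spot lameness workflow.
# Masses are computed from formulas where a formula is given; the PG 35:4
# entry carries its monoisotopic mass alongside the formula.
name,formula,monoisotopic_mass,class
Hexadecanedioic acid,C16H30O4,,fatty acid
PG 35:4,C41H71O10P,754.47849,glycerophospholipid
Alpha-carboxyethyl hydrochroman,C16H22O4,,chromanol
6-Hydroxyhexanoic acid,C6H12O3,,hydroxy fatty acid
Trans-11-methyl-2-dodecenoic acid,C13H24O2,,fatty acid
1-Piperideine-2-carboxylic acid,C6H9NO2,,amino acid derivative
Isobutylaldehyde,C4H8O,,aldehyde
Carnitine 13:3;O3,C20H33NO7,,acylcarnitine
Glucosamine,C6H13NO5,,amino sugar
Alpha-Lactose,C12H22O11,,disaccharide
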