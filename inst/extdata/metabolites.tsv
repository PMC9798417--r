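name	formula	human
arginine	C6H14N4O2	TRUE
lysine	C6H14N2O2	TRUE
putrescine	C4H12N2	TRUE
N,N-dimethylarginine	C8H18N4O2	TRUE
N,N,N-trimethyllysine	C9H20N2O2	TRUE
glucose	C6H12O6	TRUE
lactate	C3H6O3	TRUE
glutamine	C5H10N2O3	TRUE
glutamate	C5H9NO4	TRUE
proline	C5H9NO2	TRUE
leucine	C6H13NO2	TRUE
citrulline	C6H13N3O3	TRUE
hypoxanthine	C5H4N4O	TRUE
asparagine	C4H8N2O3	TRUE
alanine	C3H7NO2	TRUE
serine	C3H7NO3	TRUE
O-phosphoserine	C3H8NO6P	TRUE
cytidine	C9H13N3O5	TRUE
thymidine	C10H14N2O5	TRUE
uridine	C9H12N2O6	TRUE
uracil	C4H4N2O2	TRUE
adenine	C5H5N5	TRUE
xanthine	C5H4N4O2	TRUE
uric acid	C5H4N4O3	TRUE
guanosine	C10H13N5O5	TRUE
inosine	C10H12N4O5	TRUE
xanthosine	C10H12N4O6	TRUE
AMP	C10H14N5O7P	TRUE
UMP	C9H13N2O9P	TRUE
carnitine	C7H15NO3	TRUE
acetylcarnitine	C9H17NO4	TRUE
butyrylcarnitine	C11H21NO4	TRUE
palmitoylcarnitine	C23H45NO4	TRUE
stearoylcarnitine	C25H49NO4	TRUE
oleoylcarnitine	C25H47NO4	TRUE
spermidine	C7H19N3	TRUE
spermine	C10H26N4	TRUE
cadaverine	C5H14N2	TRUE
N-acetylputrescine	C6H14N2O	TRUE
N-acetylspermidine	C9H21N3O	TRUE
sphingosine 1-phosphate	C18H38NO5P	TRUE
S-adenosylhomocysteine	C14H20N6O5S	TRUE
caprylic acid	C8H16O2	TRUE
palmitic acid	C16H32O2	TRUE
oleic acid	C18H34O2	TRUE
linoleic acid	C18H32O2	TRUE
linolenic acid	C18H30O2	TRUE
arachidonic acid	C20H32O2	TRUE
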