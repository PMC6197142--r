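drug,n,lp_median,ft,ft_source
acetaminophen,15,1.1,1.0,computed
amiodarone,5,41.9,3.6,computed
amitriptyline,57,16.4,2.3,computed
amlodipine,9,27.8,2.9,computed
amphetamine,15,7.0,1.6,computed
bupropion,11,1.0,1.0,computed
carisoprodol,11,2.0,1.1,computed
chlorpheniramine,3,9.5,1.8,computed
citalopram,37,7.5,1.7,computed
clomipramine,5,61.0,4.3,computed
clozapine,12,6.7,1.6,computed
cyclobenzaprine,13,19.6,2.5,computed
desipramine,6,44.6,3.7,computed
dextromethorphan,4,8.6,1.8,computed
diltiazem,8,17.2,2.4,computed
diphenhydramine,54,6.7,1.6,computed
doxepin,20,19.4,2.5,computed
doxylamine,3,2.9,1.2,computed
fentanyl,16,5.9,1.5,computed
fluoxetine,48,30.0,3.1,computed
gabapentin,28,0.65,0.97,computed
guaifenesin,5,0.9,1.0,computed
hydrocodone,38,3.0,1.2,computed
hydroxyzine,10,12.3,2.0,computed
imipramine,6,28.8,3.0,computed
lamotrigine,3,8.5,1.8,computed
meprobamate,8,0.9,1.0,computed
methadone,94,4.8,1.4,computed
methamphetamine,18,6.2,1.6,computed
metoprolol,6,3.5,1.3,computed
mirtazapine,5,12.0,2.0,computed
naproxen,20,1.0,1.0,computed
olanzapine,20,12.0,2.0,computed
paroxetine,19,29.2,3.0,computed
promethazine,9,9.1,1.8,computed
propoxyphene,35,9.0,1.8,computed
propranolol,6,10.9,1.9,computed
quetiapine,65,11.2,2.0,computed
sertraline,9,76.0,4.8,computed
tramadol,36,2.3,1.1,computed
trazodone,19,2.8,1.2,computed
venlafaxine,42,3.3,1.3,computed
zolpidem,14,2.4,1.2,computed
ethanol,,,1.0,literature
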