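class,drug
glp1ra,semaglutide
glp1ra,liraglutide
glp1ra,dulaglutide
glp1ra,exenatide
glp1ra,lixisenatide
glp1ra,albiglutide
glp1ra,tirzepatide
glp1ra,loxenatide
metformin,metformin
benzodiazepines,diazepam
benzodiazepines,lorazepam
benzodiazepines,alprazolam
benzodiazepines,clonazepam
benzodiazepines,temazepam
benzodiazepines,midazolam
antidepressants,sertraline
antidepressants,fluoxetine
antidepressants,escitalopram
antidepressants,citalopram
antidepressants,paroxetine
antidepressants,venlafaxine
antidepressants,duloxetine
antidepressants,bupropion
antidepressants,mirtazapine
antidepressants,amitriptyline
antidepressants,trazodone
antipsychotics,quetiapine
antipsychotics,olanzapine
antipsychotics,risperidone
antipsychotics,aripiprazole
antipsychotics,haloperidol
opioids,morphine
opioids,oxycodone
opioids,hydrocodone
opioids,fentanyl
opioids,tramadol
opioids,codeine
sedatives,zolpidem
sedatives,zopiclone
sedatives,eszopiclone
sedatives,phenobarbital
gabaergic,gabapentin
gabaergic,pregabalin
gabaergic,baclofen
sglt2i,empagliflozin
sglt2i,dapagliflozin
sglt2i,canagliflozin
sglt2i,ertugliflozin
dpp4i,sitagliptin
dpp4i,saxagliptin
dpp4i,linagliptin
dpp4i,alogliptin
dpp4i,vildagliptin
tzd,pioglitazone
tzd,rosiglitazone
agi,acarbose
agi,miglitol
agi,voglibose
sulfonylureas,glimepiride
sulfonylureas,glipizide
sulfonylureas,glyburide
sulfonylureas,gliclazide
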