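surface,canonical,category
levothyrox,levothyrox,drug
doliprane,doliprane,drug
paracétamol,paracétamol,drug
ibuprofène,ibuprofène,drug
sertraline,sertraline,drug
metformine,metformine,drug
ventoline,ventoline,drug
cortisone,cortisone,drug
tramadol,tramadol,drug
amoxicilline,amoxicilline,drug
oméprazole,oméprazole,drug
atorvastatine,atorvastatine,drug
diabète,diabète,disease
endométriose,endométriose,disease
fibromyalgie,fibromyalgie,disease
hypothyroïdie,hypothyroïdie,disease
dépression,dépression,disease
cancer du sein,cancer du sein,disease
polyarthrite,polyarthrite,disease
asthme,asthme,disease
eczéma,eczéma,disease
lymphome,lymphome,disease
hypertension,hypertension,disease
sclérose en plaques,sclérose en plaques,disease
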