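name,percent
Sleeps,30
Eats,5
Drinks,1
Voids,1
Sexes,3
Works,25
Rests,3
Talks,5
Attends,4
Motor practices,4
Angers,1
Escapes,1
Anxious-es,2
Euphorics,2
Laughs,1
Aggresses,1
Fears fights flights,1
Interpersonal attends,8
Envies,1
Greeds,1
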