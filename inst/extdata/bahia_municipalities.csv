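code,name,lat,lon,macroregion
292740,Salvador,-12.9718,-38.5011,Leste
293330,Vitória da Conquista,-14.8615,-40.8442,Sudoeste
291480,Itabuna,-14.7856,-39.2803,Sul
291080,Feira de Santana,-12.2664,-38.9663,Centro-Leste
291360,Ilhéus,-14.7889,-39.0494,Sul
290320,Barreiras,-12.1528,-44.9908,Oeste
291840,Juazeiro,-9.4156,-40.5044,Norte
291800,Jequié,-13.8578,-40.0839,Sudoeste
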