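herb,nature,flavors,meridians,efficacy_class
huangqi,warm,sweet,spleen|lung,tonifying/qi
renshen,warm,sweet|bitter,spleen|lung|heart,tonifying/qi
baizhu,warm,sweet|bitter,spleen|stomach,tonifying/qi
fuling,neutral,sweet|bland,heart|spleen|kidney,draining/dampness
gancao,neutral,sweet,heart|lung|spleen|stomach,tonifying/qi
danggui,warm,sweet|pungent,liver|heart|spleen,tonifying/blood
chuanxiong,warm,pungent,liver|gallbladder|pericardium,invigorating/blood
baishao,cool,bitter|sour,liver|spleen,tonifying/blood
shudihuang,warm,sweet,liver|kidney,tonifying/blood
shengdihuang,cold,sweet|bitter,heart|liver|kidney,clearing/heat
guizhi,warm,pungent|sweet,heart|lung|bladder,releasing/wind_cold
rougui,hot,pungent|sweet,kidney|spleen|heart|liver,tonifying/yang
mahuang,warm,pungent|bitter,lung|bladder,releasing/wind_cold
xingren,warm,bitter,lung|large_intestine,resolving/phlegm
shigao,cold,pungent|sweet,lung|stomach,clearing/fire
zhimu,cold,bitter|sweet,lung|stomach|kidney,clearing/fire
huanglian,cold,bitter,heart|spleen|stomach|liver,clearing/damp_heat
huangqin,cold,bitter,lung|gallbladder|stomach|large_intestine,clearing/damp_heat
huangbai,cold,bitter,kidney|bladder|large_intestine,clearing/damp_heat
zhizi,cold,bitter,heart|lung|triple_burner,clearing/fire
chaihu,cool,bitter|pungent,liver|gallbladder,releasing/wind_heat
banxia,warm,pungent,spleen|stomach|lung,resolving/phlegm
shengjiang,warm,pungent,lung|spleen|stomach,releasing/wind_cold
dazao,warm,sweet,spleen|stomach,tonifying/qi
wuweizi,warm,sour|sweet,lung|heart|kidney,astringing
maidong,cool,sweet|bitter,heart|lung|stomach,tonifying/yin
tianmendong,cold,sweet|bitter,lung|kidney,tonifying/yin
danshen,cool,bitter,heart|pericardium|liver,invigorating/blood
honghua,warm,pungent,heart|liver,invigorating/blood
taoren,neutral,bitter|sweet,heart|liver|large_intestine,invigorating/blood
niuxi,neutral,bitter|sour,liver|kidney,invigorating/blood
duzhong,warm,sweet,liver|kidney,tonifying/yang
gouqizi,neutral,sweet,liver|kidney,tonifying/yin
juhua,cool,sweet|bitter,lung|liver,releasing/wind_heat
jinyinhua,cold,sweet,lung|heart|stomach,clearing/heat_toxin
lianqiao,cool,bitter,lung|heart|small_intestine,clearing/heat_toxin
jiegeng,neutral,bitter|pungent,lung,resolving/phlegm
zhiqiao,cool,bitter|pungent,spleen|stomach,regulating/qi
chenpi,warm,pungent|bitter,spleen|lung,regulating/qi
qingpi,warm,bitter|pungent,liver|gallbladder|stomach,regulating/qi
muxiang,warm,pungent|bitter,spleen|stomach|large_intestine,regulating/qi
sharen,warm,pungent,spleen|stomach|kidney,drying/dampness
houpo,warm,bitter|pungent,spleen|stomach|lung|large_intestine,drying/dampness
cangzhu,warm,pungent|bitter,spleen|stomach,drying/dampness
zexie,cold,sweet|bland,kidney|bladder,draining/dampness
zhuling,neutral,sweet|bland,kidney|bladder,draining/dampness
cheqianzi,cold,sweet,kidney|liver|lung,draining/dampness
yiyiren,cool,sweet|bland,spleen|stomach|lung,draining/dampness
shanyao,neutral,sweet,spleen|lung|kidney,tonifying/qi
shanzhuyu,warm,sour|astringent,liver|kidney,astringing
mudanpi,cool,bitter|pungent,heart|liver|kidney,clearing/heat
digupi,cold,sweet|bland,lung|kidney,clearing/deficiency_heat
xixin,warm,pungent,lung|kidney|heart,releasing/wind_cold
fangfeng,warm,pungent|sweet,bladder|liver|spleen,releasing/wind_cold
jingjie,warm,pungent,lung|liver,releasing/wind_cold
bohe,cool,pungent,lung|liver,releasing/wind_heat
sangye,cold,sweet|bitter,lung|liver,releasing/wind_heat
xuanshen,cold,sweet|bitter|salty,lung|stomach|kidney,tonifying/yin
beimu,cool,bitter|sweet,lung|heart,resolving/phlegm
suanzaoren,neutral,sweet|sour,heart|liver|gallbladder,calming/spirit
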