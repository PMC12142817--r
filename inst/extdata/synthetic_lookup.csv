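raw,standard
chaohuangqi,huangqi
chaorenshen,renshen
chaobaizhu,baizhu
chaofuling,fuling
chaogancao,gancao
chaodanggui,danggui
chaochuanxiong,chuanxiong
chaobaishao,baishao
chaoshudihuang,shudihuang
chaoshengdihuang,shengdihuang
chaoguizhi,guizhi
chaorougui,rougui
chaomahuang,mahuang
chaoxingren,xingren
chaoshigao,shigao
chaozhimu,zhimu
chaohuanglian,huanglian
chaohuangqin,huangqin
chaohuangbai,huangbai
chaozhizi,zhizi
chaochaihu,chaihu
chaobanxia,banxia
chaoshengjiang,shengjiang
chaodazao,dazao
chaowuweizi,wuweizi
chaomaidong,maidong
chaotianmendong,tianmendong
chaodanshen,danshen
chaohonghua,honghua
chaotaoren,taoren
chaoniuxi,niuxi
chaoduzhong,duzhong
chaogouqizi,gouqizi
chaojuhua,juhua
chaojinyinhua,jinyinhua
chaolianqiao,lianqiao
chaojiegeng,jiegeng
chaozhiqiao,zhiqiao
chaochenpi,chenpi
chaoqingpi,qingpi
chaomuxiang,muxiang
chaosharen,sharen
chaohoupo,houpo
chaocangzhu,cangzhu
chaozexie,zexie
chaozhuling,zhuling
chaocheqianzi,cheqianzi
chaoyiyiren,yiyiren
chaoshanyao,shanyao
chaoshanzhuyu,shanzhuyu
chaomudanpi,mudanpi
chaodigupi,digupi
chaoxixin,xixin
chaofangfeng,fangfeng
chaojingjie,jingjie
chaobohe,bohe
chaosangye,sangye
chaoxuanshen,xuanshen
chaobeimu,beimu
chaosuanzaoren,suanzaoren
huangqipian,huangqi
renshenpian,renshen
baizhupian,baizhu
fulingpian,fuling
gancaopian,gancao
dangguipian,danggui
chuanxiongpian,chuanxiong
baishaopian,baishao
shudihuangpian,shudihuang
shengdihuangpian,shengdihuang
guizhipian,guizhi
rouguipian,rougui
mahuangpian,mahuang
xingrenpian,xingren
shigaopian,shigao
zhimupian,zhimu
huanglianpian,huanglian
huangqinpian,huangqin
huangbaipian,huangbai
zhizipian,zhizi
chaihupian,chaihu
banxiapian,banxia
shengjiangpian,shengjiang
dazaopian,dazao
wuweizipian,wuweizi
maidongpian,maidong
tianmendongpian,tianmendong
danshenpian,danshen
honghuapian,honghua
taorenpian,taoren
niuxipian,niuxi
duzhongpian,duzhong
gouqizipian,gouqizi
juhuapian,juhua
jinyinhuapian,jinyinhua
lianqiaopian,lianqiao
jiegengpian,jiegeng
zhiqiaopian,zhiqiao
chenpipian,chenpi
qingpipian,qingpi
muxiangpian,muxiang
sharenpian,sharen
houpopian,houpo
cangzhupian,cangzhu
zexiepian,zexie
zhulingpian,zhuling
cheqianzipian,cheqianzi
yiyirenpian,yiyiren
shanyaopian,shanyao
shanzhuyupian,shanzhuyu
mudanpipian,mudanpi
digupipian,digupi
xixinpian,xixin
fangfengpian,fangfeng
jingjiepian,jingjie
bohepian,bohe
sangyepian,sangye
xuanshenpian,xuanshen
beimupian,beimu
suanzaorenpian,suanzaoren
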