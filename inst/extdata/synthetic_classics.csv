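formula_id,field_type,raw_term
sijunzitang,ingredient,renshen
sijunzitang,ingredient,baizhu
sijunzitang,ingredient,fuling
sijunzitang,ingredient,gancao
siwutang,ingredient,danggui
siwutang,ingredient,chuanxiong
siwutang,ingredient,baishao
siwutang,ingredient,shudihuang
bazhentang,ingredient,renshen
bazhentang,ingredient,baizhu
bazhentang,ingredient,fuling
bazhentang,ingredient,gancao
bazhentang,ingredient,danggui
bazhentang,ingredient,chuanxiong
bazhentang,ingredient,baishao
bazhentang,ingredient,shudihuang
buzhongyiqitang,ingredient,huangqi
buzhongyiqitang,ingredient,renshen
buzhongyiqitang,ingredient,baizhu
buzhongyiqitang,ingredient,gancao
buzhongyiqitang,ingredient,danggui
buzhongyiqitang,ingredient,chenpi
buzhongyiqitang,ingredient,chaihu
liuweidihuangwan,ingredient,shudihuang
liuweidihuangwan,ingredient,shanzhuyu
liuweidihuangwan,ingredient,shanyao
liuweidihuangwan,ingredient,zexie
liuweidihuangwan,ingredient,mudanpi
liuweidihuangwan,ingredient,fuling
zhibaidihuangwan,ingredient,zhimu
zhibaidihuangwan,ingredient,huangbai
zhibaidihuangwan,ingredient,shudihuang
zhibaidihuangwan,ingredient,shanzhuyu
zhibaidihuangwan,ingredient,shanyao
zhibaidihuangwan,ingredient,zexie
zhibaidihuangwan,ingredient,mudanpi
zhibaidihuangwan,ingredient,fuling
mahuangtang,ingredient,mahuang
mahuangtang,ingredient,guizhi
mahuangtang,ingredient,xingren
mahuangtang,ingredient,gancao
guizhitang,ingredient,guizhi
guizhitang,ingredient,baishao
guizhitang,ingredient,shengjiang
guizhitang,ingredient,dazao
guizhitang,ingredient,gancao
yinqiaosan,ingredient,jinyinhua
yinqiaosan,ingredient,lianqiao
yinqiaosan,ingredient,jiegeng
yinqiaosan,ingredient,bohe
yinqiaosan,ingredient,jingjie
yinqiaosan,ingredient,gancao
xiaochaihutang,ingredient,chaihu
xiaochaihutang,ingredient,huangqin
xiaochaihutang,ingredient,banxia
xiaochaihutang,ingredient,renshen
xiaochaihutang,ingredient,shengjiang
xiaochaihutang,ingredient,dazao
xiaochaihutang,ingredient,gancao
erchentang,ingredient,banxia
erchentang,ingredient,chenpi
erchentang,ingredient,fuling
erchentang,ingredient,gancao
baihutang,ingredient,shigao
baihutang,ingredient,zhimu
baihutang,ingredient,gancao
wulingsan,ingredient,zexie
wulingsan,ingredient,zhuling
wulingsan,ingredient,fuling
wulingsan,ingredient,baizhu
wulingsan,ingredient,guizhi
dangguibuxuetang,ingredient,huangqi
dangguibuxuetang,ingredient,danggui
xiaoyaosan,ingredient,chaihu
xiaoyaosan,ingredient,danggui
xiaoyaosan,ingredient,baishao
xiaoyaosan,ingredient,baizhu
xiaoyaosan,ingredient,fuling
xiaoyaosan,ingredient,gancao
xiaoyaosan,ingredient,bohe
xiaoyaosan,ingredient,shengjiang
sangjuyin,ingredient,sangye
sangjuyin,ingredient,juhua
sangjuyin,ingredient,bohe
sangjuyin,ingredient,jiegeng
sangjuyin,ingredient,xingren
sangjuyin,ingredient,lianqiao
sangjuyin,ingredient,gancao
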