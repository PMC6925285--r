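ba
pa
ma
fa
da
ta
na
la
ga
ka
ha
ja
qa
xa
zha
cha
sha
ra
za
ca
sa
ya
wa
a
bo
po
mo
fo
do
to
no
lo
go
ko
ho
jo
qo
xo
zho
cho
sho
ro
zo
co
so
yo
wo
o
be
pe
me
fe
de
te
ne
le
ge
ke
he
je
qe
xe
zhe
che
she
re
ze
ce
se
ye
we
e
bi
pi
mi
fi
di
ti
ni
li
gi
ki
hi
ji
qi
xi
zhi
chi
shi
ri
zi
ci
si
yi
wi
i
bu
pu
mu
fu
du
tu
nu
lu
gu
ku
hu
ju
qu
xu
zhu
chu
shu
ru
zu
cu
su
yu
wu
u
bai
pai
mai
fai
dai
tai
nai
lai
gai
kai
hai
jai
qai
xai
zhai
chai
shai
rai
zai
cai
sai
yai
wai
ai
bei
pei
mei
fei
dei
tei
nei
lei
gei
kei
hei
jei
qei
xei
zhei
chei
shei
rei
zei
cei
sei
yei
wei
ei
bao
pao
mao
fao
dao
tao
nao
lao
gao
kao
hao
jao
qao
xao
zhao
chao
shao
rao
zao
cao
sao
yao
wao
ao
bou
pou
mou
fou
dou
tou
nou
lou
gou
kou
hou
jou
qou
xou
zhou
chou
shou
rou
zou
cou
sou
you
wou
ou
ban
pan
man
fan
dan
tan
nan
lan
gan
kan
han
jan
qan
xan
zhan
chan
shan
ran
zan
can
san
yan
wan
an
ben
pen
men
fen
den
ten
nen
len
gen
ken
hen
jen
qen
xen
zhen
chen
shen
ren
zen
cen
sen
yen
wen
en
bang
pang
mang
fang
dang
tang
nang
lang
gang
kang
hang
jang
qang
xang
zhang
chang
shang
rang
zang
cang
sang
yang
wang
ang
beng
peng
meng
feng
deng
teng
neng
leng
geng
keng
heng
jeng
qeng
xeng
zheng
cheng
sheng
reng
zeng
ceng
seng
yeng
weng
eng
bong
pong
mong
fong
dong
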