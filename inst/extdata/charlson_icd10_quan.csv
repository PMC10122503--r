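category,prefix,weight,supersedes
mi,I21,1,
mi,I22,1,
mi,I252,1,
chf,I099,1,
chf,I110,1,
chf,I130,1,
chf,I132,1,
chf,I255,1,
chf,I420,1,
chf,I425,1,
chf,I426,1,
chf,I427,1,
chf,I428,1,
chf,I429,1,
chf,I43,1,
chf,I50,1,
chf,P290,1,
pvd,I70,1,
pvd,I71,1,
pvd,I731,1,
pvd,I738,1,
pvd,I739,1,
pvd,I771,1,
pvd,I790,1,
pvd,I792,1,
pvd,K551,1,
pvd,K558,1,
pvd,K559,1,
pvd,Z958,1,
pvd,Z959,1,
cevd,G45,1,
cevd,G46,1,
cevd,H340,1,
cevd,I60,1,
cevd,I61,1,
cevd,I62,1,
cevd,I63,1,
cevd,I64,1,
cevd,I65,1,
cevd,I66,1,
cevd,I67,1,
cevd,I68,1,
cevd,I69,1,
dementia,F00,1,
dementia,F01,1,
dementia,F02,1,
dementia,F03,1,
dementia,F051,1,
dementia,G30,1,
dementia,G311,1,
copd,I278,1,
copd,I279,1,
copd,J40,1,
copd,J41,1,
copd,J42,1,
copd,J43,1,
copd,J44,1,
copd,J45,1,
copd,J46,1,
copd,J47,1,
copd,J60,1,
copd,J61,1,
copd,J62,1,
copd,J63,1,
copd,J64,1,
copd,J65,1,
copd,J66,1,
copd,J67,1,
copd,J684,1,
copd,J701,1,
copd,J703,1,
rheumd,M05,1,
rheumd,M06,1,
rheumd,M315,1,
rheumd,M32,1,
rheumd,M33,1,
rheumd,M34,1,
rheumd,M351,1,
rheumd,M353,1,
rheumd,M360,1,
pud,K25,1,
pud,K26,1,
pud,K27,1,
pud,K28,1,
mld,B18,1,
mld,K700,1,
mld,K701,1,
mld,K702,1,
mld,K703,1,
mld,K709,1,
mld,K713,1,
mld,K714,1,
mld,K715,1,
mld,K717,1,
mld,K73,1,
mld,K74,1,
mld,K760,1,
mld,K762,1,
mld,K763,1,
mld,K764,1,
mld,K768,1,
mld,K769,1,
mld,Z944,1,
diab,E100,1,
diab,E101,1,
diab,E106,1,
diab,E108,1,
diab,E109,1,
diab,E110,1,
diab,E111,1,
diab,E116,1,
diab,E118,1,
diab,E119,1,
diab,E120,1,
diab,E121,1,
diab,E126,1,
diab,E128,1,
diab,E129,1,
diab,E130,1,
diab,E131,1,
diab,E136,1,
diab,E138,1,
diab,E139,1,
diab,E140,1,
diab,E141,1,
diab,E146,1,
diab,E148,1,
diab,E149,1,
diabwc,E102,2,diab
diabwc,E103,2,diab
diabwc,E104,2,diab
diabwc,E105,2,diab
diabwc,E107,2,diab
diabwc,E112,2,diab
diabwc,E113,2,diab
diabwc,E114,2,diab
diabwc,E115,2,diab
diabwc,E117,2,diab
diabwc,E122,2,diab
diabwc,E123,2,diab
diabwc,E124,2,diab
diabwc,E125,2,diab
diabwc,E127,2,diab
diabwc,E132,2,diab
diabwc,E133,2,diab
diabwc,E134,2,diab
diabwc,E135,2,diab
diabwc,E137,2,diab
diabwc,E142,2,diab
diabwc,E143,2,diab
diabwc,E144,2,diab
diabwc,E145,2,diab
diabwc,E147,2,diab
hp,G041,2,
hp,G114,2,
hp,G801,2,
hp,G802,2,
hp,G81,2,
hp,G82,2,
hp,G830,2,
hp,G831,2,
hp,G832,2,
hp,G833,2,
hp,G834,2,
hp,G839,2,
rend,I120,2,
rend,I131,2,
rend,N032,2,
rend,N033,2,
rend,N034,2,
rend,N035,2,
rend,N036,2,
rend,N037,2,
rend,N052,2,
rend,N053,2,
rend,N054,2,
rend,N055,2,
rend,N056,2,
rend,N057,2,
rend,N18,2,
rend,N19,2,
rend,N250,2,
rend,Z490,2,
rend,Z491,2,
rend,Z492,2,
rend,Z940,2,
rend,Z992,2,
canc,C00,2,
canc,C01,2,
canc,C02,2,
canc,C03,2,
canc,C04,2,
canc,C05,2,
canc,C06,2,
canc,C07,2,
canc,C08,2,
canc,C09,2,
canc,C10,2,
canc,C11,2,
canc,C12,2,
canc,C13,2,
canc,C14,2,
canc,C15,2,
canc,C16,2,
canc,C17,2,
canc,C18,2,
canc,C19,2,
canc,C20,2,
canc,C21,2,
canc,C22,2,
canc,C23,2,
canc,C24,2,
canc,C25,2,
canc,C26,2,
canc,C30,2,
canc,C31,2,
canc,C32,2,
canc,C33,2,
canc,C34,2,
canc,C37,2,
canc,C38,2,
canc,C39,2,
canc,C40,2,
canc,C41,2,
canc,C43,2,
canc,C45,2,
canc,C46,2,
canc,C47,2,
canc,C48,2,
canc,C49,2,
canc,C50,2,
canc,C51,2,
canc,C52,2,
canc,C53,2,
canc,C54,2,
canc,C55,2,
canc,C56,2,
canc,C57,2,
canc,C58,2,
canc,C60,2,
canc,C61,2,
canc,C62,2,
canc,C63,2,
canc,C64,2,
canc,C65,2,
canc,C66,2,
canc,C67,2,
canc,C68,2,
canc,C69,2,
canc,C70,2,
canc,C71,2,
canc,C72,2,
canc,C73,2,
canc,C74,2,
canc,C75,2,
canc,C76,2,
canc,C81,2,
canc,C82,2,
canc,C83,2,
canc,C84,2,
canc,C85,2,
canc,C88,2,
canc,C90,2,
canc,C91,2,
canc,C92,2,
canc,C93,2,
canc,C94,2,
canc,C95,2,
canc,C96,2,
canc,C97,2,
msld,I850,3,mld
msld,I859,3,mld
msld,I864,3,mld
msld,I982,3,mld
msld,K704,3,mld
msld,K711,3,mld
msld,K721,3,mld
msld,K729,3,mld
msld,K765,3,mld
msld,K766,3,mld
msld,K767,3,mld
metacanc,C77,6,canc
metacanc,C78,6,canc
metacanc,C79,6,canc
metacanc,C80,6,canc
aids,B20,6,
aids,B21,6,
aids,B22,6,
aids,B24,6,
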