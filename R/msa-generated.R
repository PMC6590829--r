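# Generated coefficient assembly for the one-Yukawa MSA factor-function
# solution obtained from the Baxter factorization of the Ornstein-Zernike
# equation with the mean-spherical closure.  The bilinear system
# P1(C,A) = 0 (linear in C) and P5(C,A) = 0 (quadratic in C) is returned
# as coefficient matrices c1[i+1,j+1]*C^i*A^j and c5[i+1,j+1]*C^i*A^j.
# Near z = 0 the closed forms cancel catastrophically in double precision,
# so exact series expansions in z are used there.
# Machine generated - do not edit by hand.
.msa_coef_matrices <- function(T, G, z) {
  if (z < 0.75) {
    x0 <- T - 24
    x1 <- 3*z
    x2 <- z^5
    x3 <- T*(T + 336)
    x4 <- 5*T
    x5 <- T*(x4 + 276)
    x6 <- 59*T
    x7 <- x6 - 192
    x8 <- 67*T - 1482
    x9 <- 1037*T - 30480
    x10 <- 1799*T - 58236
    x11 <- 3845*T - 128928
    x12 <- 4354*T - 147417
    x13 <- 100369*T - 3391152
    x14 <- 139273*T - 4669260
    x15 <- 11162880*T
    x16 <- 749587*T - 24870528
    x17 <- 491525*T - 16121754
    x18 <- 5046293*T - 163577424
    x19 <- 2119001*T - 67895220
    x20 <- 12*T
    x21 <- 48*T + 288
    x22 <- 7*T
    x23 <- T*z^3
    x24 <- -4683336365740032000*T
    x25 <- x22 - 5640
    x26 <- 464616702950400*T
    x27 <- x22 - 2280
    x28 <- 15*T - 2936
    x29 <- 17*T - 2376
    x30 <- 583*T - 64008
    x31 <- 1441*T - 131880
    x32 <- 191659*T - 15213840
    x33 <- 12025*T - 851376
    x34 <- 73189*T - 4717080
    x35 <- 4476780*T
    x36 <- 11257*T - 670680
    x37 <- 1622633*T - 90433320
    x38 <- 2*T
    x39 <- T*z^6
    x40 <- 1067062284288000*T
    x41 <- 144*T^2
    x42 <- 105859353600*T
    x43 <- 20274183401472000*T
    x44 <- 1020*T
    c1_00 <- -G*z^4*(T*x0 + 144)*((3.0/9270317056000.0)*z*(x1*(z*(x1*(x1*(z*(x1*(z*(z*(x1*(x1*(z*(x1*(x1*(z*(x1*(z*(z*(x1 + 19) + 114) + 646) + 10336) + 51680) + 723520) + 9405760) + 37623040) + 413853440) + 4138534400) + 12415603200) + 33108275200) + 231757926400) + 463515852800) + 2317579264000) + 9270317056000) + 9270317056000) + 18540634112000) + 2)
    c1_01 <- -x2*(x21 + (1.0/40548366802944000.0)*z*(2432902008176640000*T - z*(-4054836680294400*x3 + z*(-1351612226764800*x5 + z*(-96543730483200*T*x7 + z*(-48271865241600*T*x8 + z*(-1340885145600*T*x9 + z*(-268177029120*T*x10 + z*(-36569594880*T*x11 + z*(-8126576640*T*x12 + z*(-78140160*T*x13 + z*(-x14*x15 + z*(-372096*T*x16 + z*(-93024*T*x17 + z*(-1368*T*x18 + z*(-456*T*x19 + z*(x20*(332922720 - 10507613*T) + z*(24*T*(20132655 - 642253*T) + z*(T*(55005296 - 1772593*T) - 478150656) - 4303355904) - 36578525184) - 292628201472) - 2194711511040) - 15362980577280) - 99859373752320) - 599156242513920) - 3295359333826560) - 16476796669132800) - 74145585011097600) - 296582340044390400) - 1038038190155366400) - 3114114570466099200) - 7785286426165248000) - 15570572852330496000) - 23355859278495744000) + 23355859278495744000))
    c1_02 <- -x23*(144*T - 1.0/1077167364120207360000.0*z*(1077167364120207360000*T*(T - 168) + z*(1292600836944248832000*T*(T - 80) + z*(107716736412020736000*T*(x22 - 360) + z*(5129368400572416000*T*(55*T - 2184) + z*(1282342100143104000*T*(x6 - 2016) + z*(427447366714368000*T*(37*T - 1152) + z*(21372368335718400*T*(127*T - 3720) + z*(8419417829222400*T*(47*T - 1320) + z*(323823762662400*T*(155*T - 4224) + z*(8303173401600*T*(679*T - 18096) + z*(889625721600*T*(639*T - 16744) + z*(59308381440*T*(877*T - 22680) + z*(2471182560*T*(1763*T - 45120) + z*(145363680*T*(2315*T - 58752) + z*(12113640*T*(1991*T - 50184) + z*(1912680*T*(843*T - 21128) + z*(21252*T*(4753*T - 118560) + z*(3036*T*(1961*T - 48720) + z*(23*T*(14405*T - 356664) + x1*(T*(5821*T - 143704) + 850080) + 48454560) + 872182080) + 14827095360) + 237233525760) + 3558502886400) + 49819040409600) + 647647525324800) + 7771770303897600) + 85489473342873600) + 854894733428736000) + 7694052600858624000) + 61552420806868992000) + 430866945648082944000) + 2585201673888497664000) + 12926008369442488320000) + 51704033477769953280000) + 155112100433309859840000) + 310224200866619719680000) + 155112100433309859840000))
    c1_10 <- 0
    c1_11 <- x39*((1.0/11708340914350080000.0)*z*(-z*(-x24 - z*(x24 + z*(x25*x26 + z*(x26*x27 + z*(116154175737600*T*x28 + z*(38718058579200*T*x29 + z*(335221286400*T*x30 + z*(33522128640*T*x31 + z*(53721360*T*x32 + z*(161164080*T*x33 + z*(x34*x35 + z*(x35*x36 + z*(4389*T*x37 + z*(627*T*(1486531*T - 78226680) + z*(T*(113701415*T - 5692104264) + 72*z*(x38*(90269*T - 4325343) + 100925055) + 69032474280) + 621287528400) + 5280863409360) + 42245617962240) + 316822795027200) + 2217488809536000) + 14410157438476800) + 86418706748774400) + 474838270415308800) + 2369545185047040000) + 10621137829446144000) + 42150027291660288000) + 145183427337940992000) + 421500272916602880000) - 983500636805406720000) + 1686001091666411520000) + 144)
    c1_12 <- 0
    c5_00 <- 0
    c5_01 <- -T*x2*(x21 + (1.0/266765571072000.0)*z*(16005934264320000*T + z*(9603560558592000*T + z*(3734717995008000*T + z*(x40 + z*(240089013964800*T + z*(44460928512000*T + z*(6986717337600*T + z*(952734182400*T + z*(114680966400*T + z*(12350257920*T + z*(1202947200*T + z*(106928640*T + z*(8739360*T + z*(660960*T + z*(46512*T + z*(3060*T + z*(189*T + z*(11*T + 228) + 3888) + 62424) + 940032) + 13219200) + 172730880) + 2085108480) + 23096586240) + 232890577920) + 2117187072000) + 17149215283200) + 121949975347200) + 746943599001600) + 3841424223436800) + 16005934264320000) + 51218989645824000) + 115242726703104000) + 153656968937472000))
    c5_02 <- -x23*(x41 + z*(x41 - z*(x20*(24 - x4) + z*(x20*(12 - T) + z*(-T*x0 - 144)))))
    c5_10 <- z^8*(x21 + (1.0/88921857024000.0)*z*(5335311421440000*T + z*(8892185702400*x3 + z*(2964061900800*x5 + z*(211718707200*T*x7 + z*(x42*x8 + z*(2940537600*T*x9 + z*(588107520*T*x10 + z*(80196480*T*x11 + z*(17821440*T*x12 + z*(171360*T*x13 + z*(24480*T*x14 + z*(816*T*x16 + z*(204*T*x17 + z*(3*T*x18 + z*(T*x19 + 641728512) + 4812963840) + 33690746880) + 218989854720) + 1313939128320) + 7226665205760) + 36133326028800) + 162599967129600) + 650399868518400) + 2276399539814400) + 6829198619443200) + 17072996548608000) + 34145993097216000) + 51218989645824000) + 51218989645824000))
    c5_11 <- x39*(288*T + (1.0/50685458503680000.0)*z*(14597412049059840000*T - z*(x43*(T - 360) + z*(x43*(T - 120) + z*(1930874609664000*T*(x4 - 336) + z*(2896311914496000*T*(T - 49) + z*(321812434944000*T*(x38 - 81) + z*(6033983155200*T*(19*T - 680) + z*(60949324800*T*(281*T - 9240) + z*(15237331200*T*(145*T - 4488) + z*(390700800*T*(643*T - 19032) + z*(111628800*T*(229*T - 6552) + z*(x15*(211*T - 5880) + z*(232560*T*(853*T - 23280) + z*(41040*T*(375*T - 10064) + z*(1140*T*(971*T - 25704) + z*(60*T*(1237*T - 32376) + z*(T*(4661*T - 120840) + 697680) + 11162880) + 167443200) + 2344204800) + 30474662400) + 365695948800) + 4022655436800) + 40226554368000) + 362038989312000) + 2896311914496000) + 20274183401472000) + 121645100408832000) + 608225502044160000) + 2432902008176640000) + 7298706024529920000) + 14597412049059840000)))
    c5_12 <- 0
    c5_20 <- -T*z^9*((1.0/2667655710720000.0)*z*(-z*(x40 + z*(x40 + z*(-x25*x42 + z*(-x27*x42 + z*(-26464838400*T*x28 + z*(-8821612800*T*x29 + z*(-76377600*T*x30 + z*(-7637760*T*x31 + z*(-12240*T*x32 + z*(-36720*T*x33 + z*(-x34*x44 + z*(-x36*x44 + z*(-T*x37 - 1203204240) - 9625340160) - 72185644800) - 505237824000) - 3283243891200) - 19689839769600) - 108188259379200) - 539882703360000) - 2419944823296000) - 9603560558592000) - 33078930812928000) - 96035605585920000) - 224083079700480000) + 384142422343680000) + 144)
    c5_21 <- 0
    c5_22 <- 0
  } else {
    x0 <- z^4
    x1 <- T^2
    x2 <- z^2
    x3 <- 144*T
    x4 <- 24*x1
    x5 <- exp(z)
    x6 <- x1*z
    x7 <- z^3
    x8 <- x5*x7
    x9 <- T*x2
    x10 <- x5*x9
    x11 <- -24*T*x5*x7 - 144*T*x5 - 6*x1*x2*x5 - 24*x1*x5 + x1*x8 + 72*x10 + x3*z + x3 + x4 + 18*x5*x6 + 6*x6 + 144*x8
    x12 <- 2*x5
    x13 <- 144*x1
    x14 <- x1*x2
    x15 <- 288*x9
    x16 <- 144*x0
    x17 <- x3*x7
    x18 <- 24*T*x0
    x19 <- x13*z
    x20 <- x0*x1
    x21 <- 60*x14
    x22 <- 12*x1*x7
    x23 <- x13 - x15 + x16 - x17 - x18 + x19 + x20 + x21 + x22
    x24 <- -x13*x5 + 12*x14*x5 + x15*x5 + x23
    x25 <- 288*x5
    x26 <- x20*x5
    x27 <- T*x5
    x28 <- -x0*x25 + 48*x0*x27 - 2*x26
    x29 <- exp(2*z)
    x30 <- -x1*x25 + 576*x10 + x13*x29 - x15*x29 + x16*x29 + x17*x29 - x18*x29 - x19*x29 + x2*x4*x5 + x20*x29 + x21*x29 - x22*x29 + x23 + x28
    x31 <- z^5
    x32 <- T*x7
    c1_00 <- 2*G*x0*(24*T - x1 - 144)*exp(3*z)
    c1_01 <- -x11*x12*x2
    c1_02 <- T*(-x24 - x28)
    c1_10 <- 0
    c1_11 <- T*x30
    c1_12 <- 0
    c5_00 <- 0
    c5_01 <- -12*x27*x31*(T*z + 4*T + 24*z + 24)
    c5_02 <- -x23*x32
    c5_10 <- x11*x12*x31
    c5_11 <- 2*x32*(-x16*x5 + x18*x5 + x24 - x26)
    c5_12 <- 0
    c5_20 <- -x30*x32
    c5_21 <- 0
    c5_22 <- 0
  }
  list(c1 = matrix(c(c1_00, c1_01, c1_02, c1_10, c1_11, c1_12), 2, 3, byrow = TRUE),
       c5 = matrix(c(c5_00, c5_01, c5_02, c5_10, c5_11, c5_12, c5_20, c5_21, c5_22), 3, 3, byrow = TRUE))
}
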