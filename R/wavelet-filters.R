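# Decomposition low-pass filters for the supported orthogonal wavelet families.
# Standard published filter banks (Daubechies, symlet, coiflet, discrete Meyer);
# the high-pass filter is the quadrature mirror g[k] = (-1)^k h[L-1-k].
# dmey is a 512-tap FIR sampled from the exact Meyer conjugate mirror
# filter (QMF deviation ~1.6e-9, so periodized packet energy is conserved
# to well below 1e-8 over levels 1..7).
.wavelet_filters <- list(
  db1 = c(
    0.70710678118654757, 0.70710678118654757),
  db2 = c(
    -0.12940952255126037, 0.22414386804201339, 0.83651630373780794, 0.48296291314453416),
  db3 = c(
    0.035226291885709533, -0.085441273882026658, -0.13501102001025458, 0.45987750211849154,
    0.80689150931109255, 0.33267055295008263),
  db4 = c(
    -0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309,
    -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
  db5 = c(
    0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744, 0.077571493840045719,
    -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.72430852843777294,
    0.60382926979718965, 0.16010239797419293),
  db6 = c(
    -0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613, -0.03158203931748603,
    0.027522865530305727, 0.097501605587323043, -0.12976686756726194, -0.22626469396543983,
    0.31525035170919763, 0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db8 = c(
    -0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705, -0.0048703529934515741,
    0.0087460940474057766, 0.013981027917398282, -0.044088253930794755, -0.017369301001807547,
    0.12874742662047847, 0.00047248457391328279, -0.28401554296154691, -0.015829105256349306,
    0.58535468365420673, 0.67563073629728976, 0.31287159091429995, 0.054415842243104008),
  db16 = c(
    -2.1093396301007431e-08, 2.3087840868575457e-07, -7.3636567854512051e-07, -1.0435713423116066e-06,
    1.1336608661276258e-05, -1.3945668988208893e-05, -6.103596621410936e-05, 0.00017478724522533817,
    0.00011424152003872239, -0.00094102174935956756, 0.00040789698084971285, 0.003128023381206269,
    -0.0036442796214983899, -0.0069900145634139163, 0.013993768859828731, 0.01029765964095597,
    -0.036888397691730142, -0.0075889743688577378, 0.075924236044276311, -0.006239722752474872,
    -0.1323883055638104, 0.027340263752716042, 0.2111906939471043, -0.027918208133028276,
    -0.32706331052791771, -0.089751089402489645, 0.44029025688635692, 0.63735633208378895,
    0.4303127228460038, 0.16506428348885313, 0.034907714323673344, 0.0031892209253477381),
  db32 = c(
    -9.4210191395350789e-16, 2.000715303810525e-14, -1.6638004894334023e-13, 5.3614822296118021e-13,
    1.0756106535010622e-12, -1.4309187651692024e-11, 3.2632707413329079e-11, 8.9047237962216058e-11,
    -5.8810914626346055e-10, 4.3843877999404743e-10, 4.2504223119805926e-09, -1.104383021722649e-08,
    -1.2199243594833731e-08, 8.9659663119577288e-08, -5.0033618687482301e-08, -4.2859706931514572e-07,
    7.5600476255959481e-07, 1.2028890363216209e-06, -4.5583095762644234e-06, -6.3617815322602555e-07,
    1.8242684019806914e-05, -1.2940457794055127e-05, -5.2598092826843231e-05, 8.1036783291348383e-05,
    0.00010539154617398281, -0.00030596544238269119, -0.00010245373106073962, 0.0008673058518450555,
    -0.00022116787295790979, -0.0019647405558217783, 0.0014689551004684678, 0.0036272246406878648,
    -0.0046492167511844118, -0.0054115682572757912, 0.011017400715406881, 0.006167527310685675,
    -0.021662822836391194, -0.0041459076608272184, 0.037051457923544681, -0.0023802644649325738,
    -0.056926314062478438, 0.014106151516106608, 0.080874140638483957, -0.029627872508447704,
    -0.10945611311608938, 0.044404908199939738, 0.14523207947528666, -0.048995117184671741,
    -0.1921023447085469, 0.024662444839697404, 0.24831064235688016, 0.064713354805516238,
    -0.27742158155842722, -0.26669818147667557, 0.12063053826561783, 0.47780916373394838,
    0.53431791934095385, 0.36750962859734965, 0.17575078363943891, 0.060257499120335373,
    0.014681046381419136, 0.0024312619195722661, 0.00024665669063809033, 1.1614633021350149e-05),
  sym2 = c(
    -0.12940952255092145, 0.22414386804185735, 0.83651630373746899, 0.48296291314469025),
  sym8 = c(
    -0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981, 0.0076074873249176054,
    -0.14329423835080971, -0.061273359067658524, 0.48135965125837221, 0.77718575170052351,
    0.3644418948353314, -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
    0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668, 0.0018899503327594609),
  sym16 = c(
    6.2300067012207606e-06, -3.1135564076219692e-06, -0.00010943147929529757, 2.8078582128442894e-05,
    0.00085235471080470952, -0.0001084456223089688, -0.0038809122526038786, 0.00071821197883178923,
    0.012666731659857348, -0.0031265171722710075, -0.031051202843553064, 0.0048692744049046071,
    0.032333091610663785, -0.066983049070217779, -0.034574228416972504, 0.39712293362064416,
    0.75652498787569711, 0.47534280601152273, -0.054040601387606135, -0.15959219218520598,
    0.03072113906330156, 0.078037852903419913, -0.0035102750683740089, -0.024952758046290123,
    0.001359844742484172, 0.0069377611308027096, -0.00022211647621176323, -0.0013387206066921965,
    3.656592483348223e-05, 0.00016545679579108483, -5.3964831793152419e-06, -1.0797982104319795e-05),
  coif1 = c(
    -0.015655728135791993, -0.07273261951252645, 0.38486484686485778, 0.85257202021160039,
    0.33789766245748182, -0.07273261951252645),
  coif3 = c(
    -3.4599773197272781e-05, -7.0983302506379004e-05, 0.00046621695982040288, 0.0011175187708306303,
    -0.0025745176881367972, -0.0090079761367306242, 0.015880544863669452, 0.034555027573297738,
    -0.082301927106299827, -0.071799821619154838, 0.42848347637737, 0.79377722262608719,
    0.40517690240911824, -0.061123390002972552, -0.065771911281469364, 0.023452696142077168,
    0.0077825964256727463, -0.0037935128643808019),
  dmey = c(
    3.7864743146233182e-10, 2.0583278248936416e-11, -4.1477659688431565e-10, 4.0150777484402828e-10,
    2.2096423256435631e-11, -4.402973247200904e-10, 4.2602945467220422e-10, 2.3744228045153025e-11,
    -4.6770624356270757e-10, 4.523867676547641e-10, 2.5533480616305168e-11, -4.972097428343943e-10,
    4.8070667160685308e-10, 2.7486211807189952e-11, -5.2895067304696777e-10, 5.1120116093471849e-10,
    2.9610669110325725e-11, -5.6318121966974542e-10, 5.4402353313204511e-10, 3.1934551099700955e-11,
    -6.0007419241721307e-10, 5.794329005394622e-10, 3.4467915879621837e-11, -6.399393228335247e-10,
    6.1761520687534669e-10, 3.724580052394113e-11, -6.8298661972034541e-10, 6.588887749311699e-10,
    4.0280518038117107e-11, -7.2959854313622319e-10, 7.0348022649723e-10, 4.3616664457144287e-11,
    -7.8003153462271275e-10, 7.5178274287477551e-10, 4.7269349232261409e-11, -8.3476055225934798e-10,
    8.0407390176928246e-10, 5.1295724008781925e-11, -8.9410030386116995e-10, 8.6084210997494158e-10,
    5.5714418664464039e-11, -9.5864416907710805e-10, 9.2242915649907352e-10, 6.0599155107078866e-11,
    -1.0287803991694589e-09, 9.8944537782791039e-10, 6.5972987563731954e-11, -1.1052550306758913e-09,
    1.0623139635418092e-09, 7.1931723769804958e-11, -1.1885496956726688e-09, 1.1418024589004678e-09,
    7.8503999045640933e-11, -1.2796086746365704e-09, 1.228437907978233e-09, 8.5815285630286662e-11,
    -1.3790329243465758e-09, 1.3231920334990803e-09, 9.3901260723840484e-11, -1.4880261717527136e-09,
    1.4267252914102222e-09, 1.0292761262603954e-10, -1.6073428641131429e-09, 1.5402766441220725e-09,
    1.1293893725011894e-10, -1.738529085441788e-09, 1.6646791409348793e-09, 1.2415593836398714e-10,
    -1.8825381122527934e-09, 1.8015244118665355e-09, 1.3663451593716712e-10, -2.041371762330133e-09,
    1.9518704982640113e-09, 1.5067139383596773e-10, -2.2162427655558815e-09, 2.1177784911822365e-09,
    1.6633679409376466e-10, -2.4097652861088447e-09, 2.3006020994807477e-09, 1.8403360799552748e-10,
    -2.623493263117942e-09, 2.5030331714549045e-09, 2.0385016174909332e-10, -2.8608718625806731e-09,
    2.7268172876847769e-09, 2.2633931043766699e-10, -3.1239074348751338e-09, 2.9755021824702352e-09,
    2.5161213127344931e-10, -3.4171849454214225e-09, 3.2513575703507833e-09, 2.8043589621867354e-10,
    -3.7433158053800387e-09, 3.5591048671814894e-09, 3.1294996997586929e-10, -4.1084662560141672e-09,
    3.9017216693651077e-09, 3.5023221760328337e-10, -4.5160643418526767e-09, 4.2855571600508017e-09,
    3.9245650623160436e-10, -4.9744970854582294e-09, 4.7145549750654295e-09, 4.411569421991013e-10,
    -5.4883053866846808e-09, 5.1973493572316727e-09, 4.9654804253482474e-10, -6.0690366231581907e-09,
    5.7392170973099332e-09, 5.6084429021578731e-10, -6.7227636980099201e-09, 6.3520422828590151e-09,
    6.3430500012456876e-10, -7.4655959987227727e-09, 7.0429637500210052e-09, 7.2017594516136858e-10,
    -8.3057381792687588e-09, 7.8285529731212689e-09, 8.1875891820078965e-10, -9.2659874174700853e-09,
    8.7185835488628969e-09, 9.348907593140327e-10, -1.0357548270394654e-08, 9.736491276395185e-09,
    1.0688971127178781e-09, -1.161318799865922e-08, 1.0895830805676689e-08, 1.2281171665659362e-09,
    -1.3048382929603481e-08, 1.2230257185025813e-08, 1.4128441640607531e-09, -1.471103826463061e-08,
    1.3758835111586317e-08, 1.6344363735404386e-09, -1.662278849199526e-08, 1.5530708546478547e-08,
    1.8930149524670478e-09, -1.8854988788968874e-08, 1.7573108113138961e-08, 2.2065435933808367e-09,
    -2.1438264504030457e-08, 1.9959117096385475e-08, 2.5746488439822359e-09, -2.4481106657941822e-08,
    2.2728294786878756e-08, 3.0264292301453455e-09, -2.8027436738455579e-08, 2.5991524789068556e-08,
    3.5602927604387046e-09, -3.2246004801682219e-08, 2.9807367809779609e-08, 4.2246419395364256e-09,
    -3.7200644431016999e-08, 3.4347813919602688e-08, 5.0150498952127318e-09, -4.3160566149076541e-08,
    3.9701395650519407e-08, 6.0144462104331828e-09, -5.021977080841315e-08, 4.614147826371978e-08,
    7.2119267361009678e-09, -5.8820084680769175e-08, 5.3805131168127804e-08, 8.7543704307709459e-09,
    -6.9101631738137562e-08, 6.3138790110708318e-08, 1.0616020899073084e-08, -8.1813066477556587e-08,
    7.4360551704353992e-08, 1.306695265090963e-08, -9.7165300714081332e-08, 8.8221868653293515e-08,
    1.6046723637576108e-08, -1.1647371142920872e-07, 1.0508103645648658e-07, 2.0073574551840345e-08,
    -1.4005702323768771e-07, 1.2624641152600025e-07, 2.500356163213276e-08, -1.70324151551228e-07,
    1.52329603333068e-07, 3.1881045504991313e-08, -2.0775247711975551e-07, 1.8569655408543584e-07,
    4.0352507875194598e-08, -2.5696975680841086e-07, 2.2744194063686515e-07, 5.2645572838565837e-08,
    -3.1866274887671816e-07, 2.8202957992315437e-07, 6.7851809233749422e-08, -4.0223183401427367e-07,
    3.5154175511731284e-07, 9.1050308685135401e-08, -5.085402030839737e-07, 4.4480705707086255e-07,
    1.1976148112274951e-07, -6.5798165795333224e-07, 5.6612314392430401e-07, 1.6652188710648718e-07,
    -8.5110604489157195e-07, 7.3386959186526384e-07, 2.240153291086177e-07, -1.1357795738018072e-06,
    9.5798511755800486e-07, 3.2630373324977852e-07, -1.509704805774757e-06, 1.2787778278657093e-06,
    4.4953968329965109e-07, -2.0965344907161601e-06, 1.7232343345976835e-06, 6.9803813953571223e-07,
    -2.8793749675993608e-06, 2.3831587127646476e-06, 9.8247298768785118e-07, -4.2177568018485212e-06,
    3.3535111665818729e-06, 1.6746802590500727e-06, -6.0344691050367634e-06, 4.83756432320716e-06,
    2.4022472356965025e-06, -9.5562762208074147e-06, 7.2165344061198204e-06, 4.8490367992000013e-06,
    -1.4206892519675844e-05, 1.0503918453429683e-05, 6.1875388275072313e-06, -2.4437962703328182e-05,
    2.0106384212809917e-05, 1.499347595768228e-05, -4.642870438489382e-05, 3.2341298666098357e-05,
    3.7409600756987594e-05, -0.0001027789003882374, 2.446195021206341e-05, 0.00014971335982404404,
    -7.5592788602316834e-05, -0.00013991302095187882, -9.3512851016676083e-05, 0.00016118970797392301,
    0.0008594995285858216, -0.00057818535774864814, -0.002702166518011708, 0.0021947735657375312,
    0.0060455056480884801, -0.0063867234070981767, -0.01104463290478393, 0.015250900724818699,
    0.017403874074711903, -0.032094037241224643, -0.024321764212951402, 0.063667249127492498,
    0.030621219057689109, -0.13269650748289635, -0.035048258873640881, 0.44409466964876165,
    0.74375040006195436, 0.44409466964876165, -0.035048258873640881, -0.1326965074828963,
    0.030621219057689102, 0.063667249127492498, -0.024321764212951402, -0.032094037241224643,
    0.017403874074711903, 0.015250900724818696, -0.011044632904783927, -0.006386723407098175,
    0.0060455056480884783, 0.0021947735657375307, -0.0027021665180117075, -0.00057818535774864803,
    0.00085949952858582149, 0.00016118970797392125, -9.3512851016676381e-05, -0.00013991302095187923,
    -7.5592788602316373e-05, 0.00014971335982404477, 2.4461950212063305e-05, -0.00010277890038823756,
    3.7409600756987594e-05, 3.2341298666094956e-05, -4.6428704384894362e-05, 1.4993475957682999e-05,
    2.0106384212809687e-05, -2.4437962703328412e-05, 6.1875388275070983e-06, 1.0503918453426629e-05,
    -1.4206892519675844e-05, 4.8490367992006857e-06, 7.2165344061196967e-06, -9.5562762208079585e-06,
    2.4022472356961285e-06, 4.8375643232078809e-06, -6.0344691050366795e-06, 1.6746802590520064e-06,
    3.3535111665818725e-06, -4.2177568018523862e-06, 9.8247298768802757e-07, 2.3831587127653206e-06,
    -2.8793749675991617e-06, 6.9803813953548628e-07, 1.7232343345978067e-06, -2.0965344907168776e-06,
    4.4953968329966136e-07, 1.2787778278678446e-06, -1.509704805774325e-06, 3.26303733250168e-07,
    9.5798511755814271e-07, -1.1357795738017693e-06, 2.2401532910874814e-07, 7.3386959186168142e-07,
    -8.5110604489168672e-07, 1.6652188710607828e-07, 5.6612314392441635e-07, -6.5798165795319132e-07,
    1.1976148112276645e-07, 4.4480705707081793e-07, -5.085402030839628e-07, 9.1050308686593489e-08,
    3.5154175511731284e-07, -4.0223183401801841e-07, 6.7851809233608682e-08, 2.8202957992247081e-07,
    -3.1866274887679571e-07, 5.2645572838437485e-08, 2.2744194063671594e-07, -2.5696975680778532e-07,
    4.0352507875085973e-08, 1.8569655408407392e-07, -2.0775247711983539e-07, 3.1881045505953172e-08,
    1.5232960333308335e-07, -1.7032415155080578e-07, 2.5003561631917617e-08, 1.2624641152320464e-07,
    -1.4005702323768263e-07, 2.0073574550511155e-08, 1.0508103645665743e-07, -1.1647371142897016e-07,
    1.6046723637676898e-08, 8.8221868653072386e-08, -9.716530071415202e-08, 1.3066952651627117e-08,
    7.4360551704354005e-08, -8.1813066477159461e-08, 1.0616020899219554e-08, 6.3138790110532241e-08,
    -6.910163173838553e-08, 8.7543704314583114e-09, 5.380513116821217e-08, -5.8820084679310081e-08,
    7.2119267361007065e-09, 4.6141478262255631e-08, -5.0219770808453437e-08, 6.0144462108228676e-09,
    3.9701395650336441e-08, -4.3160566149417696e-08, 5.015049895237046e-09, 3.4347813918434894e-08,
    -3.7200644431017118e-08, 4.2246419404131527e-09, 2.9807367809713229e-08, -3.2246004801922948e-08,
    3.5602927605628276e-09, 2.5991524788854627e-08, -2.8027436738495181e-08, 3.0264292270515453e-09,
    2.2728294786874991e-08, -2.4481106658709571e-08, 2.574648843825888e-09, 1.9959117096316439e-08,
    -2.1438264503848166e-08, 2.2065435939451318e-09, 1.7573108113093039e-08, -1.8854988791757399e-08,
    1.8930149524374215e-09, 1.5530708548672535e-08, -1.6622788492092553e-08, 1.6344363744668694e-09,
    1.375883511135866e-08, -1.4711038264606277e-08, 1.4128441638781368e-09, 1.2230257185661703e-08,
    -1.3048382929603482e-08, 1.2281171653434034e-09, 1.0895830805746941e-08, -1.1613187998667084e-08,
    1.0688971126191827e-09, 9.7364912764503662e-09, -1.0357548270439989e-08, 9.348907608179579e-10,
    8.7185835488078745e-09, -9.265987415910873e-09, 8.1875891842012072e-10, 7.8285529733454662e-09,
    -8.3057381791547733e-09, 7.2017594530060231e-10, 7.0429637501557116e-09, -7.4655959989018639e-09,
    6.3430500011700843e-10, 6.3520422818476867e-09, -6.7227636979816752e-09, 5.6084428958941699e-10,
    5.7392170975447897e-09, -6.0690366232010949e-09, 4.96548042568765e-10, 5.1973493566962933e-09,
    -5.4883053866846824e-09, 4.4115694371652582e-10, 4.7145549750691642e-09, -4.9744970856029281e-09,
    3.9245650618440244e-10, 4.2855571600942634e-09, -4.5160643417505331e-09, 3.5023221782648585e-10,
    3.9017216693648662e-09, -4.1084662551645204e-09, 3.1294996982900141e-10, 3.5591048681356695e-09,
    -3.7433158054526693e-09, 2.8043589632636057e-10, 3.2513575704920343e-09, -3.4171849472972588e-09,
    2.5161213127323548e-10, 2.9755021816471673e-09, -3.12390743508045e-09, 2.2633930978567129e-10,
    2.726817287518746e-09, -2.8608718626679779e-09, 2.0385016178694531e-10, 2.5030331715918492e-09,
    -2.6234932631123263e-09, 1.8403360772557745e-10, 2.3006020994318427e-09, -2.4097652861908717e-09,
    1.6633679408349971e-10, 2.117778491201236e-09, -2.2162427658429504e-09, 1.5067139256103418e-10,
    1.9518704982280017e-09, -2.0413717637203593e-09, 1.3663451624654549e-10, 1.8015244111887884e-09,
    -1.8825381122407091e-09, 1.2415593809959951e-10, 1.6646791406668542e-09, -1.7385290854240531e-09,
    1.1293893725011893e-10, 1.5402766451171402e-09, -1.6073428636935747e-09, 1.0292761345622427e-10,
    1.4267252915693295e-09, -1.4880261710476097e-09, 9.3901260543171933e-11, 1.3231920353803913e-09,
    -1.3790329244664851e-09, 8.5815288094733016e-11, 1.2284379082678856e-09, -1.2796086747771334e-09,
    7.8503999090077153e-11, 1.1418024587269698e-09, -1.1885496958726282e-09, 7.193172534284037e-11,
    1.0623139635594695e-09, -1.1052550313357986e-09, 6.5972987773502722e-11, 9.8944537758012264e-10,
    -1.0287803991443135e-09, 6.0599154943326198e-11, 9.2242915603581164e-10, -9.5864416977112437e-10,
    5.5714418664229158e-11, 8.6084211162338619e-10, -8.9410030378127475e-10, 5.1295724348781591e-11,
    8.0407390190781939e-10, -8.3476055237353313e-10, 4.7269348909314439e-11, 7.5178274223236709e-10,
    -7.8003153462250461e-10, 4.3616664289474725e-11, 7.0348022645372774e-10, -7.2959854334303292e-10,
    4.0280518117571734e-11, 6.588887751976666e-10, -6.8298661962166555e-10, 3.7245802525369627e-11,
    6.1761520687528237e-10, -6.3993932107217107e-10, 3.446791568657462e-11, 5.7943290046299845e-10,
    -6.0007419235450595e-10, 3.1934551191854756e-11, 5.4402353350388864e-10, -5.631812191532646e-10,
    2.9610669113660271e-11, 5.1120116155581253e-10, -5.2895067331043761e-10, 2.7486212174718108e-11,
    4.8070667155367777e-10, -4.9720974275686804e-10, 2.5533481057122554e-11, 4.5238676838567696e-10,
    -4.6770624367737724e-10, 2.3744228237745665e-11, 4.2602945460095192e-10, -4.402973244530933e-10,
    2.2096423053217663e-11, 4.0150777463012516e-10, -4.1477659683638234e-10, 2.0583281132764125e-11)
)
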