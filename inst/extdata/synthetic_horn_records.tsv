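id	harvest_year	age	segments	circumferences
I001	2015	7	148.2633393583819,195.8557319513342,81.9899071983156,59.8739427651488,58.1507314343618,49.0096416886540,41.4350613699821	161.939590496276,202.424488120345,246.375738551710,267.758369108727,283.598013435409,289.560291975113,298.523284653088
I002	2016	10	245.9184373589233,199.0648512172078,86.0022789295582,61.0499285522397,57.3225553798692,47.4952711463394,39.3030033353421,38.7040127978523,25.6404744804726,24.6986608215464	158.332473845435,197.915592306794,240.735213226417,264.645207914815,282.822081445711,285.830237655384,292.774632342961,293.237498039016,297.908010414444,294.290422179008
I003	2014	11	147.7322774659842,196.0248930770395,74.7626040073464,70.1350481868700,54.5802576222149,48.1526828294067,36.7492194718190,33.4001062537901,31.7187110085864,25.5178498437731,25.3749990962931	158.992948469795,198.741185587244,241.499991783065,267.692422359047,279.955013561448,287.424389184728,290.081886835653,296.264820052037,296.106147170970,300.767175342199,298.180506781406
I004	2019	13	135.7021441916004,198.6178760715833,74.1853238622903,64.5274609411475,54.8602656421500,51.5497022955681,37.1360943729699,39.3597471516811,28.9066034964318,22.3377876633409,17.7435200723494,26.7731082584704,18.1956971427492	159.022753477623,198.778441847029,240.790904128196,267.473125200462,279.709150219702,285.174811502168,292.860886937592,295.364781814003,296.129350028798,295.787089223503,300.461633414670,297.280348076269,298.354882680858
I005	2011	8	132.8705121204257,197.0517212096146,67.2758405152945,69.7985123418839,57.2043698541913,47.8309805743577,38.7043333772805,36.7364290625117	163.779764645823,204.724705807279,241.662309634677,268.941864600763,279.598673482423,289.169107049575,294.483257603193,296.413181698656
I006	2011	7	149.7967714117840,203.5759588007253,73.1987826952890,60.1341496241641,63.1337189013772,44.8271742694453,43.0599605539634	155.860098263689,194.825122829611,236.436189599263,263.139105509078,274.441508808113,287.646737343254,290.124108893343
I007	2014	6	120.3762536589056,191.8528473682774,75.6624204598420,64.1177077137916,59.1665021171012,51.4672953091795	158.859722415012,198.574653018766,246.404064586886,264.788788432873,280.368008401380,287.536333948550
I008	2013	8	119.3965942924842,194.3197513408336,76.1134453212749,65.4028859916152,57.4434092894817,46.5940726739872,45.6745428939533,26.2904883464253	156.118358088766,195.147947610958,238.524422876054,264.242101339725,273.436621894146,286.621245468001,285.727298257745,290.756954559555
I009	2012	7	128.9496821165085,195.5272245454117,81.9082791758542,64.8239325604466,52.1923431762843,50.9630984940947,39.4222224824206	158.941120874569,198.676401093212,239.757351698874,265.666486875425,278.062324094336,288.651713695304,286.290952872170
I010	2016	7	278.0048335948959,197.2374475734756,76.9947060302945,68.3834456170992,56.1543269443888,46.8476959394917,40.4139490178223	162.195725972288,202.744657465361,240.374505191045,265.457610621646,283.851508492984,289.329042620781,290.912734251239
I011	2014	12	118.9199401438236,206.2199962395387,70.4166324819341,70.7999368196159,56.5575092183365,44.4588445403089,42.0812222894843,30.3534033707860,29.7810571539775,24.1881983575709,29.9079093125483,17.0727386667734	161.041620082312,201.302025102890,241.549361541953,266.980324403332,281.482810893022,290.998149343447,291.378459595540,294.615775209242,298.943212606513,297.198446572169,298.019650247220,299.817602438132
I012	2015	12	140.5047734174877,205.1067059887306,71.8825658073866,72.9032473478308,50.1745620436255,54.2801799866250,34.9726971401930,36.7480388843055,26.8718665492169,25.8305267194246,22.5745559033442,16.6777574761493	161.771699206066,202.214624007582,245.044812004405,270.780058081246,281.509971801283,291.757170483589,294.211984739730,300.426239657105,297.784244011638,300.768921602262,299.978020481611,303.305769848927
I013	2016	11	236.7812255583704,199.4071268787858,75.4264908982208,68.8089643354287,54.3559033851563,42.7323928391535,41.7238030792782,31.8755224131265,43.6693332642483,16.7848619094858,20.9889934018699	159.714393583392,199.642991979240,241.069745572135,263.710501623666,279.665686140214,288.829812725714,287.635637441051,294.209923575269,295.526026116037,300.152422294464,296.584058847176
I014	2016	11	121.7866521282122,198.5687662263271,76.4352395863593,67.9746215262610,54.1690138038702,42.5139253639408,46.0169459335758,32.9660277651730,32.1628881294504,19.9803418835766,22.9692794746045	157.831532529192,197.289415661491,241.315050135301,261.004507150617,276.640086178181,290.355851447582,286.737167337324,293.943316307776,295.075401633409,296.999831198299,298.016434888102
I015	2016	12	124.0267327520996,200.4439089208322,75.0408310408356,66.2654816830005,57.9129020512769,39.7723985059792,46.5694848909050,38.3866292770802,27.0096297848991,25.2292822163955,23.3058946550140,17.4586143636824	159.192316271654,198.990395339568,242.105879757758,265.902918862583,280.678496126448,290.289927931617,291.629298114332,293.774962906136,298.564116945207,299.640748105440,299.913444977552,295.454188209978
I016	2014	10	104.3369327019900,189.9276688833018,74.5302766603953,73.5023306220686,56.7367099364810,42.3345943762372,39.3850267233561,38.2855527392288,26.9927703120840,27.9626035367666	158.170250305021,197.712812881276,242.910103058655,268.926245136784,278.981883146721,289.834740453020,294.375224494710,294.563042207022,297.353740993739,296.166620093339
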