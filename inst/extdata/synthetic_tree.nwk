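((((Genus15_sp03:1.787570583,((((Genus08_sp06:0.3992820454,(Genus05_sp02:0.02838210625,Genus09_sp02:0.02838210625):0.3708999392):0.3921428601,(Genus05_sp01:0.4270179054,Genus15_sp04:0.4270179054):0.3644070001):0.2936105468,(Genus13_sp12:0.3298875978,(Genus01_sp08:0.1556747034,Genus08_sp05:0.1556747034):0.1742128944):0.7551478546):0.4614629692,Genus14_sp03:1.546498422):0.241072161):1.932176732,((Genus13_sp02:2.846693509,((Genus13_sp08:0.4242524999,(Genus05_sp06:0.1802940484,Genus12_sp03:0.1802940484):0.2439584514):1.707922863,Genus01_sp05:2.132175363):0.7145181465):0.4765704206,(Genus10_sp03:1.193486547,((((Genus02_sp03:0.09389215179,Genus09_sp11:0.09389215179):0.3406171074,Genus06_sp06:0.4345092592):0.2976940672,Genus07_sp02:0.7322033264):0.4474088046,Genus02_sp04:1.179612131):0.01387441579):2.129777383):0.396483385):0.5415749117,(((Genus13_sp10:0.08336157093,Genus14_sp11:0.08336157093):0.2538001393,Genus09_sp01:0.3371617103):1.340668504,((Genus09_sp09:0.5721473102,(Genus01_sp03:0.08399049987,Genus11_sp01:0.08399049987):0.4881568103):0.4149458167,(((((Genus12_sp01:0.4440763486,(Genus08_sp02:0.3880894223,Genus14_sp10:0.3880894223):0.05598692626):0.06272241168,((Genus10_sp05:0.02963294887,Genus15_sp02:0.02963294887):0.1696668445,Genus10_sp06:0.1992997934):0.3074989669):0.07762500765,Genus02_sp01:0.5844237679):0.08972684033,Genus05_sp07:0.6741506083):0.2699977267,((Genus11_sp02:0.6677649051,Genus09_sp06:0.6677649051):0.1336436256,(((Genus09_sp05:0.08888115535,Genus11_sp04:0.08888115535):0.5119577757,(Genus13_sp01:0.3899954922,Genus04_sp01:0.3899954922):0.2108434388):0.1974197575,(Genus07_sp05:0.5551208883,Genus04_sp04:0.5551208883):0.2431378002):0.003149842231):0.1427398043):0.04294479186):0.6907370874):2.583492012):0.1933769896,((((Genus13_sp03:0.5636445028,Genus01_sp01:0.5636445028):2.137321707,(Genus03_sp07:0.04010656894,Genus05_sp04:0.04010656894):2.660859641):0.3431973572,(((Genus09_sp03:0.9709049978,Genus07_sp07:0.9709049978):0.4730679441,(Genus15_sp06:0.1418943148,Genus13_sp04:0.1418943148):1.302078627):0.7361576776,(Genus07_sp04:0.3389549504,Genus11_sp07:0.3389549504):1.841175669):0.8640329477):0.1099456563,((((((((Genus02_sp02:0.2194134004,(Genus09_sp07:0.1153026135,Genus08_sp01:0.1153026135):0.1041107869):0.3713730219,Genus04_sp02:0.5907864222):0.2604754394,(Genus15_sp08:0.1586534319,(Genus08_sp03:0.1373903876,Genus03_sp06:0.1373903876):0.02126304433):0.6926084297):0.1277275327,(Genus09_sp12:0.2714702244,Genus14_sp04:0.2714702244):0.7075191699):0.6286010847,(Genus11_sp08:1.325877771,Genus06_sp08:1.325877771):0.2817127083):0.4092105133,((Genus14_sp08:0.2156926847,Genus07_sp01:0.2156926847):0.304265595,Genus06_sp01:0.5199582797):1.496842713):0.4772397566,((((Genus06_sp02:0.2624786449,Genus09_sp10:0.2624786449):0.3492607237,(Genus03_sp03:0.293510336,Genus03_sp04:0.293510336):0.3182290326):0.3502372402,((Genus13_sp05:0.1738213884,(Genus05_sp05:0.05225583033,Genus01_sp04:0.05225583033):0.1215655581):0.5424208946,Genus14_sp09:0.716242283):0.2457343257):0.844492124,(((Genus12_sp04:0.5325588638,(Genus11_sp06:0.001644695965,Genus14_sp05:0.001644695965):0.5309141679):0.09445507334,Genus08_sp04:0.6270139372):1.132293013,((Genus13_sp11:1.330557494,(((Genus06_sp07:0.07238495347,(Genus11_sp03:0.000483461,Genus03_sp05:0.000483461):0.07190149247):0.6719784378,(Genus01_sp07:0.4509846418,Genus05_sp03:0.4509846418):0.2933787495):0.2756979885,(Genus03_sp02:0.7353279984,(Genus12_sp02:0.2607208273,Genus06_sp05:0.2607208273):0.4746071711):0.2847333814):0.3104961141):0.4132536018,((Genus09_sp04:0.5896819256,(Genus11_sp05:0.1527976308,Genus13_sp06:0.1527976308):0.4368842948):0.02261133293,Genus14_sp06:0.6122932585):1.131517837):0.01549585425):0.04716178289):0.6875720162):0.08239454981,((Genus11_sp10:1.456760242,((Genus11_sp11:0.5366746171,Genus01_sp02:0.5366746171):0.4275090833,((Genus10_sp04:0.1936591997,Genus10_sp01:0.1936591997):0.3065348948,Genus07_sp06:0.5001940945):0.4639896058):0.492576542):0.3980844588,(Genus09_sp08:0.03962759884,Genus04_sp05:0.03962759884):1.815217102):0.7215905976):0.5776739248):1.300589992);
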