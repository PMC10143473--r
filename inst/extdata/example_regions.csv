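"region_id","province","city","industry_type","sampling_year","depth_cm","cr_conc","source"
"R00001","Shaanxi",,"E-w",2005,36.9,1137.67633310923,"synthetic"
"R00002","Shanxi",,"S",2008,31.5,195.977588801489,"synthetic"
"R00003","Hebei",,"El",2012,9.8,769.664575353819,"synthetic"
"R00004","Shanghai",,"El",2015,30.4,232.106356564175,"synthetic"
"R00005","Qinghai",,"S",2012,14.6,37.8122154934788,"synthetic"
"R00006","Hubei",,"El",2010,21.4,470.856573365383,"synthetic"
"R00007","Zhejiang",,"S",2016,48.2,56.7745308637563,"synthetic"
"R00008","Jiangsu",,"S",2003,49.4,229.899567323679,"synthetic"
"R00009","Beijing",,"E-w",2009,41.3,117.267852357574,"synthetic"
"R00010","Beijing",,"M",2011,6.7,32.356379663493,"synthetic"
"R00011","Yunnan",,"E-w",2020,39.5,11.4076699551194,"synthetic"
"R00012","Liaoning",,"C",2003,43.6,12007.3905106288,"synthetic"
"R00013","Hunan",,"El",2018,48.1,59.2335438255332,"synthetic"
"R00014","Hubei",,"S",2015,38.1,79.2295794650493,"synthetic"
"R00015","Shandong",,"S",2003,30,46.3332820283362,"synthetic"
"R00016","Liaoning",,"E-w",2012,22.2,33.0600293657303,"synthetic"
"R00017","Guangxi",,"M",2002,41.4,268.649627570874,"synthetic"
"R00018","Fujian",,"E-w",2003,38.2,190.483317178127,"synthetic"
"R00019","Sichuan",,"M",2004,43.4,53.1094341188298,"synthetic"
"R00020","Anhui",,"M",2014,13.5,152.489990009372,"synthetic"
"R00021","Jilin",,"M",2006,10.7,66.2193609920684,"synthetic"
"R00022","Zhejiang",,"M",2006,33.4,62.5523545302288,"synthetic"
"R00023","Jiangsu",,"El",2003,26.7,64.1213835007491,"synthetic"
"R00024","Hebei",,"E-w",2018,36.6,53.1638654898059,"synthetic"
"R00025","Jiangsu",,"E-w",2005,49.6,82.1586040211277,"synthetic"
"R00026","Ningxia",,"M",2017,9.1,40.3591753015512,"synthetic"
"R00027","Inner Mongolia",,"El",2010,45.2,127.930113417569,"synthetic"
"R00028","Beijing",,"E-w",2019,32.1,18.2804444631152,"synthetic"
"R00029","Jiangsu",,"M",2003,15,34.6947074594365,"synthetic"
"R00030","Shanghai",,"M",2014,42.7,107.583656678593,"synthetic"
"R00031","Liaoning",,"S",2011,5.1,52.8404404919337,"synthetic"
"R00032","Jilin",,"M",2002,17.3,54.5578112974161,"synthetic"
"R00033","Shandong",,"M",2020,33.3,9.97051851108188,"synthetic"
"R00034","Hubei",,"T",2002,20.9,1081.89221806376,"synthetic"
"R00035","Shanghai",,"El",2019,22.1,392.140543831594,"synthetic"
"R00036","Hebei",,"El",2002,7.8,81.1081851896685,"synthetic"
"R00037","Shanghai",,"M",2009,15.7,32.3094348509858,"synthetic"
"R00038","Heilongjiang",,"T",2009,49.7,3479.95282500426,"synthetic"
"R00039","Hebei",,"M",2017,32.7,52.7408921829333,"synthetic"
"R00040","Tibet",,"El",2011,7.2,246.229689070924,"synthetic"
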