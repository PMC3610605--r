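[{"scenario":"path4a","category":"4","levels":{"sSA":120000,"sRAa":100000,"sRE":80000,"sTE":60000}},{"scenario":"path4b","category":"4","levels":{"sSA":120000,"sRAb":100000,"sRE":80000,"sTE":60000}},{"scenario":"path4c","category":"4","levels":{"sSB":120000,"sVB":100000,"sVE":80000,"sTE":60000}},{"scenario":"path6a","category":"6","levels":{"sSB":120000,"sUB":108000,"sUD":96000,"sVD":84000,"sVE":72000,"sTE":60000}},{"scenario":"path8a","category":"8","levels":{"sSB":120000,"sUB":111428.571428571,"sUC":102857.142857143,"sPC":94285.7142857143,"sPD":85714.2857142857,"sVD":77142.8571428571,"sVE":68571.4285714286,"sTE":60000}},{"scenario":"path10a","category":"10","levels":{"sSB":120000,"sUB":113333.333333333,"sUC":106666.666666667,"sQC":100000,"sQFa":93333.3333333333,"sPF":86666.6666666667,"sPD":80000,"sVD":73333.3333333333,"sVE":66666.6666666667,"sTE":60000}},{"scenario":"path10b","category":"10","levels":{"sSB":120000,"sUB":113333.333333333,"sUC":106666.666666667,"sQC":100000,"sQFb":93333.3333333333,"sPF":86666.6666666667,"sPD":80000,"sVD":73333.3333333333,"sVE":66666.6666666667,"sTE":60000}},{"scenario":"loop","category":"LOOP","levels":{"sSB":90000,"sUB":80000,"sUD":70000,"sVD":65000,"sVB":60000}},{"scenario":"none","category":"NONE","levels":[]}]
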