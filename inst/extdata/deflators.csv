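year,index
2003,74
2004,75.900000000000006
2005,77.599999999999994
2006,79.900000000000006
2007,82.299999999999997
2008,84.700000000000003
2009,85.900000000000006
2010,87.200000000000003
2011,88.799999999999997
2012,90.200000000000003
2013,92
2014,93.299999999999997
2015,93.799999999999997
2016,95.700000000000003
2017,97.599999999999994
2018,100
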