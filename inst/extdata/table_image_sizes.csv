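size_label,count
1804x2136,5338
2136x2304,2050
2140x3044,4000
2144x2304,7179
2148x2304,1524
Others,83
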