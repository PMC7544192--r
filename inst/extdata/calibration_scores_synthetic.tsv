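class	mismatch_pct
clean	20.4783258594918
clean	20.6383909051159
clean	20.7835642618251
clean	20.4833597464342
clean	20.3811294445736
clean	19.9632437399495
clean	20.5077152812344
clean	20.3370530630836
clean	20.0168563000421
clean	20.0630045284505
clean	19.56419868791
clean	19.4503621644653
clean	20.7829338025072
clean	21.7581998474447
clean	19.7920677705044
clean	19.8046875
clean	20.1895184683814
clean	20.1022146507666
clean	20.850040096231
clean	19.3296319144561
clean	19.9901768172888
clean	19.9580810433163
clean	19.8892761943818
clean	20.1931518876207
clean	20.0833742030407
clean	20.8639705882353
clean	21.0454234193107
clean	18.9036769681931
clean	19.6159455517744
clean	20.5547794851327
clean	19.9877750611247
clean	20.4813591316659
clean	20.0284427589476
clean	20.5527847049044
clean	19.9614736335179
clean	19.5075355550838
clean	20.3531045427495
clean	20.6499193362526
clean	20.1233981964879
clean	20.2600426935766
clean	20.3314370516943
clean	19.706944149501
clean	21.1495193291062
clean	19.5953625824051
clean	20.2886065044153
clean	20.7799655897534
clean	20.4793545325107
clean	20.7870837537841
clean	20.68891741549
clean	20.5992509363296
clean	20.066692820714
clean	19.7333968102833
clean	20.2028740490279
clean	20.2015869611838
clean	19.7478137075452
clean	20.6816421378776
clean	19.3008792622775
clean	20.4426559356137
clean	18.9522998296423
clean	20.6729800523877
contaminated	21.9307450157398
contaminated	21.8224852071006
contaminated	20.9347145266201
contaminated	20.7701863354037
contaminated	21.9013237063779
contaminated	21.9591659426586
contaminated	21.6392020815265
contaminated	22.9104305779415
contaminated	21.2716313435738
contaminated	21.8707328174784
contaminated	21.7765603600078
contaminated	21.6909501333881
contaminated	22.570345240471
contaminated	21.8815865108258
contaminated	20.7882882882883
contaminated	21.4660743134087
contaminated	21.7692974848222
contaminated	21.127385707945
contaminated	21.944177093359
contaminated	22.7972027972028
contaminated	21.3878713878714
contaminated	20.3575547866205
contaminated	21.6888126875268
contaminated	21.7025257249766
contaminated	22.0017444395988
contaminated	21.3148788927336
contaminated	21.243153131698
contaminated	21.5214148732154
contaminated	22.5644699140401
contaminated	21.5542521994135
contaminated	21.9839641991423
contaminated	21.4473418233273
contaminated	21.251193887297
contaminated	20.5989304812834
contaminated	21.3267813267813
contaminated	21.1288292068821
contaminated	21.1317073170732
contaminated	22.4162151314469
contaminated	22.192513368984
contaminated	20.8871157005398
contaminated	22.0779220779221
contaminated	21.0287081339713
contaminated	20.7866453235765
contaminated	22.1192052980132
contaminated	20.849845882871
contaminated	22.2195704057279
contaminated	22.0840586918677
contaminated	20.6937561942517
contaminated	21.4316239316239
contaminated	22.1150059078377
contaminated	20.6582077716098
contaminated	22.8591320491993
contaminated	22.2298065984073
contaminated	20.2309754588575
contaminated	22.4789071916432
contaminated	21.326803205699
contaminated	22.0084467386204
contaminated	22.03426124197
contaminated	20.8599651365485
contaminated	21.6553536238231
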