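week	imaged_networks	analyzed_networks	analyzed_rois	synchronous_networks	synchronous_rois
1	7	5	3496	NA	NA
2	13	4	2132	NA	NA
3	11	4	2136	3	1358
4	11	4	2018	2	1216
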