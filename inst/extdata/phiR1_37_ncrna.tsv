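# Unannotated RNA species identified in the bacteriophage phiR1-37 genome
# (262,391 bp). Coordinates 1-based inclusive; relation is the position of
# the transcript with reference to annotated genes.
name	contig	start	end	strand	relation
misc_1	phiR1-37	14254	14383	-	antisense to 3' end of g048
misc_2	phiR1-37	17805	18199	+	antisense to 5' end of g055 and 3' end of g056
misc_3	phiR1-37	32500	32820	-	antisense to 5' end of g077
misc_4	phiR1-37	61640	61936	+	intragenic region between g099 and g100
misc_5	phiR1-37	91090	91192	-	antisense to middle part of g144
misc_6	phiR1-37	103380	103720	+	antisense to g157 and 5' end of g156
misc_7	phiR1-37	148610	148960	+	antisense to 5' end of g207
misc_8	phiR1-37	160970	161280	+	antisense to middle part of g230
misc_9	phiR1-37	217379	217553	+	antisense to middle part of g295
misc_10	phiR1-37	242633	242957	-	antisense to middle part of g326
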