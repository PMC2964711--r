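# Haplogroup N1a subclade definitions.
#
# Tokens use motif nomenclature (HVS-I minus 16000). "@" marks a
# back-mutation diagnostic (the ancestral diagnostic at that position is
# expected to have reverted). Weights tune the matching evidence: highly
# specific markers (16086, HVS-II 207) are upweighted, the hypervariable
# 16189 and the widespread HVS-II 152/199/204 background are downweighted,
# the recurrent loss of 16172 on the N1a1a2 stem is a soft diagnostic.
near_tolerance: 1
clades:
  "N":
    parent: null
    hvs2: ["73", "263"]
    weights: {"73": 0, "263": 0}
  N1a:
    parent: "N"
    hvs1: ["147G", "172", "223", "248", "355"]
    coding: ["2702"]
  N1a1:
    parent: N1a
    hvs1: ["147A"]
    coding: ["3336"]
  N1a1a:
    parent: N1a1
    hvs1: ["320"]
  N1a1a1:
    parent: N1a1a
    coding: ["@2702", "8164", "9300"]
  N1a1a1a:
    parent: N1a1a1
    hvs1: ["189"]
    coding: ["6641"]
    weights: {"189": 0.5}
  N1a1a2:
    parent: N1a1a
    hvs1: ["86", "@172"]
    hvs2: ["152", "199", "204", "207"]
    weights: {"86": 2, "@172": 0.5, "152": 0.25, "199": 0.25, "204": 0.25, "207": 2}
  N1a1a3:
    parent: N1a1a
    hvs1: ["154"]
  N1a1b:
    parent: N1a1
    anti_hvs1: ["320"]
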