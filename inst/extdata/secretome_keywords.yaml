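# Secretome categorisation keywords (lowercase substrings of annotations).
# Priority at assignment: not_secreted overrides everything, then
# mucosal > proteolytic > other_hydrolytic > other. Proteins matching no
# keyword are treated as not secreted. This list encodes a curation policy,
# not an algorithm: edit it to change category membership.
not_secreted:
  - actin
  - tubulin
  - histone
  - ribosom
  - calpain
  - proteasome
  - elongation factor
  - enolase
  - aldolase
  - heat shock
  - ubiquitin
  - 14-3-3
  - glyceraldehyde-3-phosphate
  - mitochondri
  - cytoplasmic
  - nuclear
  - atp synthase
mucosal:
  - mucin
  - gastrokine
  - trefoil
  - mucosa
proteolytic:
  - pepsin
  - gastricsin
  - chymosin
  - progastricsin
  - cathepsin
  - peptidase
  - protease
  - proteinase
other_hydrolytic:
  - phospholipase
  - lipase
  - lysozyme
  - amylase
  - nuclease
  - esterase
  - glycosidase
  - hydrolase
other:
  - intrinsic factor
  - anhydrase
  - cystatin
  - transcobalamin
  - secretoglobin
  - lectin
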