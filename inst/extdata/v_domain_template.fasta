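>Vtemplate synthetic IMGT-gapped V-domain numbering template (dots = unoccupied positions; 104 numbered positions + 3 germline CDR3 anchor residues)
GQSVTQPEKLLSVAEGDSIVINCTYSDRGSQSFF....ILWYRQYPNKGPELLLKVTENKE....DGRFTAQLNKASQYVSLLIRDSQLSDSATYFAVSESTYCAVS
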