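# Clan assignment snapshot: family_accession <TAB> clan_accession
# Families absent from this table belong to no clan.
# Refresh with: rfamtools refresh-clans --out FILE
RF00005	CL00001
RF03117	CL00116
RF03120	CL00116
RF03122	CL00117
RF03125	CL00117
RF00165	CL00117
RF00164	CL00117
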