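>B2I role=HA_RAMP family=brevinin helix=1-33
LKKLLGKIAKFVKKVVGTLKGVVKQIFKFAKQV
>MII role=HA_RAMP family=magainin helix=1-23
LQNFLSKIFKVVKKAVKKAKQFF
>R2G role=HA_RAMP family=ranatuerin helix=1-28
FKTLLNKVAGFATKIAQTVKSALTGFLQ
>DS4 role=HA_RAMP family=dermaseptin helix=3-28
GTAKKVITKIIKAIKKAFKKAQQVFKKV
>DDM role=HA_RAMP family=dermadistinctin helix=1-23
LKKIIKGLIKFINKFFKTVSTFL
>B1E role=HA_RAMP family=brevinin helix=1-24
AGKFLSTIAKAATKIASKVTGILK
>CP3 role=HA_RAMP family=cecropin helix=4-30
GGTVKKIVGTIVTAVNSVVGNVKSVVKKFF
>S1D role=HA_RAMP family=sarcotoxin helix=5-39
TGTKIKNAVKKAAGAVQKILGSFKKAISQVVKAFSGAVQ
>E1S role=HA_RAMP family=esculentin helix=9-40
TGTPATGTAGKILTNAIKIFGTFIKKLKQALKGVAQVISK
>LCA role=HA_RAMP family=leucocin helix=7-37
PPGKPSFNKVLGKVLKVFSNVVQGIKKILKNILKAFT
>SIM role=HA_RAMP family=moricin helix=11-42
PGGPPSAPSAVKKFVQKLVQAVKSFIGKLQKAAKKIFQILKG
>B15 role=HA_RAMP family=bacillocin helix=8-35
GGKAGSAISKFAKTLFTAVQTLFKKLKKILNTAAK
>EHF role=HA_RAMP family=enterocin helix=13-44
ATPSSKATGTGGANKIATGIVKLFKTAVTTLKTLFNKIINIFSK
>RCA1_cTP role=cTP cleavage=45 family=rubisco_activase helix=16-35
GAPRAGTARSTPGPAVRRILGRAAQAAQNLIGGLQPPAGGPRGGAPTRRGGPTRTSTGTRSRATASPR
>CAG2_mTP role=mTP cleavage=32 family=carbonic_anhydrase helix=1-28
FRNALNRAVRAVNRVLTSLTNVAGRVFSGSGSSTGGGSSSPSRTASRGGGTRGPT
>RP1 role=RANDOM
RHHTMWIFYQISGNSYYSVGMKVNPYYFTM
>RP2 role=RANDOM
FLKMLGKFFTTQCVYNKTLVLYFYMFQLAG
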