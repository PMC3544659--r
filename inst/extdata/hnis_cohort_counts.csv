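subtype,grade,n
ER+PgR+HER2-,2+,14
ER+PgR+HER2-,1+,9
ER+PgR+HER2-,0,2
ER+PgR+HER2+,2+,4
ER+PgR+HER2+,1+,5
ER+PgR+HER2+,0,2
ER-PgR-HER2+,2+,7
ER-PgR-HER2+,1+,12
ER-PgR-HER2+,0,8
ER-PgR-HER2-,2+,8
ER-PgR-HER2-,1+,17
ER-PgR-HER2-,0,20
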