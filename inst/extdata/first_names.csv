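NAME,SEX,WEIGHT
MARY,F,100
PATRICIA,F,80
JENNIFER,F,78
LINDA,F,75
ELIZABETH,F,74
BARBARA,F,70
SUSAN,F,66
JESSICA,F,64
SARAH,F,62
KAREN,F,60
LISA,F,58
NANCY,F,57
BETTY,F,55
MARGARET,F,54
SANDRA,F,52
ASHLEY,F,51
KIMBERLY,F,50
EMILY,F,49
DONNA,F,48
MICHELLE,F,47
CAROL,F,45
AMANDA,F,44
DOROTHY,F,43
MELISSA,F,42
DEBORAH,F,41
STEPHANIE,F,40
REBECCA,F,39
SHARON,F,38
LAURA,F,37
CYNTHIA,F,36
KATHLEEN,F,35
AMY,F,34
ANGELA,F,33
SHIRLEY,F,32
ANNA,F,31
BRENDA,F,30
PAMELA,F,29
EMMA,F,28
NICOLE,F,27
HELEN,F,26
SAMANTHA,F,25
KATHERINE,F,24
CHRISTINE,F,23
DEBRA,F,22
RACHEL,F,21
CAROLYN,F,20
JANET,F,19
CATHERINE,F,18
MARIA,F,17
HEATHER,F,16
DIANE,F,15
RUTH,F,14
JULIE,F,13
OLIVIA,F,12
JOYCE,F,11
VIRGINIA,F,10
VICTORIA,F,9
KELLY,F,8
LAUREN,F,7
CHRISTINA,F,6
JAMES,M,100
ROBERT,M,95
JOHN,M,92
MICHAEL,M,90
DAVID,M,85
WILLIAM,M,80
RICHARD,M,75
JOSEPH,M,70
THOMAS,M,68
CHARLES,M,65
CHRISTOPHER,M,62
DANIEL,M,60
MATTHEW,M,58
ANTHONY,M,55
MARK,M,53
DONALD,M,50
STEVEN,M,48
PAUL,M,46
ANDREW,M,44
JOSHUA,M,42
KENNETH,M,40
KEVIN,M,38
BRIAN,M,36
GEORGE,M,34
EDWARD,M,32
RONALD,M,30
TIMOTHY,M,28
JASON,M,26
JEFFREY,M,24
RYAN,M,22
JACOB,M,20
GARY,M,19
NICHOLAS,M,18
ERIC,M,17
JONATHAN,M,16
STEPHEN,M,15
LARRY,M,14
JUSTIN,M,13
SCOTT,M,12
BRANDON,M,11
BENJAMIN,M,10
SAMUEL,M,9
GREGORY,M,8
FRANK,M,7
ALEXANDER,M,6
RAYMOND,M,5
PATRICK,M,5
JACK,M,4
DENNIS,M,4
JERRY,M,3
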