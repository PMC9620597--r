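NAME,WEIGHT
SMITH,100
JOHNSON,80
WILLIAMS,70
BROWN,62
JONES,61
GARCIA,60
MILLER,52
DAVIS,48
RODRIGUEZ,45
MARTINEZ,43
HERNANDEZ,40
LOPEZ,38
GONZALEZ,37
WILSON,35
ANDERSON,33
THOMAS,32
TAYLOR,31
MOORE,30
JACKSON,29
MARTIN,28
LEE,27
PEREZ,26
THOMPSON,25
WHITE,24
HARRIS,23
SANCHEZ,22
CLARK,21
RAMIREZ,20
LEWIS,19
ROBINSON,18
WALKER,17
YOUNG,16
ALLEN,15
KING,14
WRIGHT,13
SCOTT,12
TORRES,12
NGUYEN,11
HILL,11
FLORES,10
GREEN,10
ADAMS,9
NELSON,9
BAKER,9
HALL,8
RIVERA,8
CAMPBELL,8
MITCHELL,7
CARTER,7
ROBERTS,7
GOMEZ,6
PHILLIPS,6
EVANS,6
TURNER,6
DIAZ,5
PARKER,5
CRUZ,5
EDWARDS,5
COLLINS,5
REYES,4
STEWART,4
MORRIS,4
MORALES,4
MURPHY,4
COOK,4
ROGERS,3
GUTIERREZ,3
ORTIZ,3
MORGAN,3
COOPER,3
PETERSON,3
BAILEY,3
REED,3
KELLY,2
HOWARD,2
RAMOS,2
KIM,2
COX,2
WARD,2
RICHARDSON,2
WATSON,2
BROOKS,2
CHAVEZ,2
WOOD,2
JAMES,2
BENNETT,1
GRAY,1
MENDOZA,1
RUIZ,1
HUGHES,1
PRICE,1
ALVAREZ,1
CASTILLO,1
SANDERS,1
PATEL,1
MYERS,1
LONG,1
ROSS,1
FOSTER,1
JIMENEZ,1
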