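"subject","group","age_group","test","block","cascades"
"S01","sleep_first","adolescent",1,1,12
"S01","sleep_first","adolescent",1,2,19
"S01","sleep_first","adolescent",1,3,26
"S01","sleep_first","adolescent",2,1,24
"S01","sleep_first","adolescent",2,2,22
"S01","sleep_first","adolescent",2,3,24
"S01","sleep_first","adolescent",3,1,20
"S01","sleep_first","adolescent",3,2,25
"S01","sleep_first","adolescent",3,3,25
"S02","wake_first","adult",1,1,22
"S02","wake_first","adult",1,2,26
"S02","wake_first","adult",1,3,31
"S02","wake_first","adult",1,4,32
"S02","wake_first","adult",1,5,37
"S02","wake_first","adult",2,1,26
"S02","wake_first","adult",2,2,28
"S02","wake_first","adult",2,3,28
"S02","wake_first","adult",2,4,26
"S02","wake_first","adult",2,5,30
"S02","wake_first","adult",3,1,29
"S02","wake_first","adult",3,2,29
"S02","wake_first","adult",3,3,31
"S02","wake_first","adult",3,4,29
"S02","wake_first","adult",3,5,28
"S03","sleep_first","adolescent",1,1,27
"S03","sleep_first","adolescent",1,2,27
"S03","sleep_first","adolescent",1,3,31
"S03","sleep_first","adolescent",2,1,26
"S03","sleep_first","adolescent",2,2,29
"S03","sleep_first","adolescent",2,3,30
"S03","sleep_first","adolescent",3,1,27
"S03","sleep_first","adolescent",3,2,31
"S03","sleep_first","adolescent",3,3,31
"S04","wake_first","adult",1,1,8
"S04","wake_first","adult",1,2,10
"S04","wake_first","adult",1,3,12
"S04","wake_first","adult",1,4,13
"S04","wake_first","adult",1,5,10
"S04","wake_first","adult",2,1,16
"S04","wake_first","adult",2,2,15
"S04","wake_first","adult",2,3,16
"S04","wake_first","adult",2,4,16
"S04","wake_first","adult",2,5,18
"S04","wake_first","adult",3,1,14
"S04","wake_first","adult",3,2,17
"S04","wake_first","adult",3,3,16
"S04","wake_first","adult",3,4,17
"S04","wake_first","adult",3,5,17
"S05","sleep_first","adolescent",1,1,15
"S05","sleep_first","adolescent",1,2,17
"S05","sleep_first","adolescent",1,3,24
"S05","sleep_first","adolescent",2,1,17
"S05","sleep_first","adolescent",2,2,19
"S05","sleep_first","adolescent",2,3,23
"S05","sleep_first","adolescent",3,1,21
"S05","sleep_first","adolescent",3,2,25
"S05","sleep_first","adolescent",3,3,29
"S06","wake_first","adult",1,1,13
"S06","wake_first","adult",1,2,16
"S06","wake_first","adult",1,3,24
"S06","wake_first","adult",1,4,26
"S06","wake_first","adult",1,5,29
"S06","wake_first","adult",2,1,21
"S06","wake_first","adult",2,2,20
"S06","wake_first","adult",2,3,23
"S06","wake_first","adult",2,4,22
"S06","wake_first","adult",2,5,22
"S06","wake_first","adult",3,1,23
"S06","wake_first","adult",3,2,23
"S06","wake_first","adult",3,3,24
"S06","wake_first","adult",3,4,22
"S06","wake_first","adult",3,5,24
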